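#' Relation-label to polarity vocabulary
#'
#' Network files frequently encode causality as free-text relation labels
#' (`"activation"`, `"inhibition"`, `"association"`, ...) rather than signed
#' integers. A polarity vocabulary maps each label to `+1` or `-1`. A label
#' not present in the mapping is an error unless a default polarity is
#' configured; the shipped default vocabulary follows the common convention
#' of curated drug-protein-disease networks in which protein-disease and
#' protein-phenotype *associations* lack explicit causal annotation and are
#' inferred to be activations.
#'
#' @param mapping Named numeric vector, names are relation labels, values
#'   `+1` or `-1`.
#' @param default Polarity to assign to unmapped labels (`NA`, the default,
#'   makes unmapped labels an error).
#' @return An object of class `polarity_vocabulary`.
#' @examples
#' vocab <- polarity_vocabulary(c(binds = 1, represses = -1))
#' @export
polarity_vocabulary <- function(mapping, default = NA_real_) {
  mapping <- unlist(mapping)
  stopifnot(is.numeric(mapping), !is.null(names(mapping)))
  if (!all(mapping %in% c(-1, 1))) {
    stop("vocabulary polarities must be +1 or -1", call. = FALSE)
  }
  if (!is.na(default) && !default %in% c(-1, 1)) {
    stop("`default` must be +1, -1, or NA", call. = FALSE)
  }
  structure(list(mapping = mapping, default = default),
    class = "polarity_vocabulary"
  )
}

#' @rdname polarity_vocabulary
#' @param default_association Map unmapped labels to `+1` (the
#'   association-as-activation convention). Equivalent to `default = 1`.
#' @export
default_vocabulary <- function(default_association = TRUE) {
  polarity_vocabulary(
    c(
      "activation" = 1, "increases" = 1, "->" = 1,
      "inhibition" = -1, "decreases" = -1, "-|" = -1,
      "association" = 1
    ),
    default = if (default_association) 1 else NA_real_
  )
}

#' @export
print.polarity_vocabulary <- function(x, ...) {
  cat("<polarity_vocabulary> ", length(x$mapping), " labels",
    if (!is.na(x$default)) {
      paste0(", unmapped labels default to ", sprintf("%+d", x$default))
    } else {
      ", unmapped labels are an error"
    }, "\n",
    sep = ""
  )
  invisible(x)
}

#' Read a polarity vocabulary from a JSON or TSV mapping file
#'
#' JSON files hold an object `{"label": 1, "label2": -1, ...}` (optionally a
#' top-level `{"mapping": {...}, "default": 1}`); TSV files hold two columns
#' `label<TAB>polarity` without a header.
#'
#' @param path File path; format inferred from the `.json`/`.tsv` extension.
#' @param default Default polarity for unmapped labels (overridden by a
#'   `default` entry in a JSON file).
#' @return A [polarity_vocabulary()].
#' @export
read_vocabulary <- function(path, default = NA_real_) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (is.list(obj) && "mapping" %in% names(obj)) {
      default <- if (!is.null(obj$default)) as.numeric(obj$default) else default
      mapping <- unlist(obj$mapping)
    } else {
      mapping <- unlist(obj)
    }
  } else {
    tab <- readr::read_tsv(path,
      col_names = c("label", "polarity"),
      col_types = "cd", progress = FALSE
    )
    mapping <- stats::setNames(tab$polarity, tab$label)
  }
  polarity_vocabulary(mapping, default = default)
}

# internal: map relation labels to polarities, honouring the default
apply_vocabulary <- function(labels, vocab) {
  stopifnot(inherits(vocab, "polarity_vocabulary"))
  pol <- unname(vocab$mapping[labels])
  if (anyNA(pol)) {
    if (is.na(vocab$default)) {
      bad <- unique(labels[is.na(pol)])
      stop(
        "unmapped relation label(s): ", paste(bad, collapse = ", "),
        " (configure a default polarity to accept them)",
        call. = FALSE
      )
    }
    pol[is.na(pol)] <- vocab$default
  }
  pol
}
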