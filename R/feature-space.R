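#' Discrete or real-valued feature space
#'
#' The functional domain a particle measure is defined over: an ordered set of
#' categorical labels (genes, cell types, atlas regions) or, for real-valued
#' features, labels paired with numeric values.
#'
#' @param labels Character vector of unique, non-empty feature identifiers.
#' @param kind Either `"discrete"` (categorical labels compared by identity)
#'   or `"real"` (labels carry numeric values compared by Euclidean product).
#' @param values Optional numeric vector (one per label), required when
#'   `kind = "real"`.
#' @return An object of class `feature_space`.
#' @export
feature_space <- function(labels, kind = c("discrete", "real"), values = NULL) {
  kind <- match.arg(kind)
  labels <- as.character(labels)
  if (length(labels) < 1L) stop("a feature space needs at least one label")
  if (anyDuplicated(labels)) stop("feature labels must be unique")
  if (any(!nzchar(labels))) stop("feature labels must be non-empty strings")
  if (kind == "real") {
    if (is.null(values) || length(values) != length(labels) || !is.numeric(values))
      stop("'values' must be numeric, one per label, for a real-valued feature space")
  }
  structure(list(labels = labels, kind = kind, values = values),
            class = "feature_space")
}

#' @export
print.feature_space <- function(x, ...) {
  cat(sprintf("<feature_space> %s, |F| = %d: %s\n", x$kind, length(x$labels),
              paste(utils::head(x$labels, 6L), collapse = ", ")))
  invisible(x)
}

#' @export
length.feature_space <- function(x) length(x$labels)

same_feature_space <- function(a, b) {
  identical(a$labels, b$labels) && identical(a$kind, b$kind)
}
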