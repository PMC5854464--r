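#' Labelled exact probability mass functions
#'
#' A `pmf` pairs character labels (phenotype classes, marker sets, genotype
#' keys) with exact [rational()] probabilities. Used for every distribution
#' the package reports.
#'
#' @param labels character vector of outcome labels (unique).
#' @param probs [rational()] vector of the same length.
#' @return A `pmf`.
#' @export
pmf <- function(labels, probs) {
  probs <- as_rational(probs)
  stopifnot(is.character(labels), length(labels) == length(probs))
  if (anyDuplicated(labels)) stop("pmf labels must be unique", call. = FALSE)
  structure(list(labels = labels, probs = probs), class = "pmf")
}

#' @export
length.pmf <- function(x) length(x$labels)

#' Probability of one outcome (exact; zero if the label is absent)
#' @param x a `pmf`.
#' @param label outcome label.
#' @return rational scalar.
#' @export
pmf_prob <- function(x, label) {
  i <- match(label, x$labels)
  if (is.na(i)) rational(0) else x$probs[i]
}

#' Total probability mass (exact)
#' @param x a `pmf`.
#' @return rational scalar.
#' @export
pmf_total <- function(x) {
  if (length(x$labels) == 0L) return(rational(0))
  sum(x$probs)
}

#' Reorder/align a pmf to a label universe, filling zeros
#' @param x a `pmf`.
#' @param labels target label order.
#' @return A `pmf` over exactly `labels`.
#' @export
pmf_align <- function(x, labels) {
  probs <- rational(rep(0, length(labels)))
  for (i in seq_along(labels)) probs[i] <- pmf_prob(x, labels[i])
  pmf(labels, probs)
}

#' Accumulate mass into a pmf under a label mapping
#' @keywords internal
.pmf_accumulate <- function(labels, probs) {
  u <- unique(labels)
  out <- rational(rep(0, length(u)))
  for (i in seq_along(labels)) {
    k <- match(labels[i], u)
    out[k] <- out[k] + probs[i]
  }
  pmf(u, out)
}

#' @export
as.data.frame.pmf <- function(x, ...) {
  data.frame(label = x$labels,
             fraction = format(x$probs),
             probability = as.numeric(x$probs),
             percent = 100 * as.numeric(x$probs),
             stringsAsFactors = FALSE)
}

#' @export
format.pmf <- function(x, ...) {
  paste0("<pmf: ", paste(sprintf("%s=%s", x$labels, format(x$probs)),
                         collapse = ", "), ">")
}

#' @export
print.pmf <- function(x, ...) {
  df <- as.data.frame(x)
  df$percent <- sprintf("%.4g%%", df$percent)
  print(df, row.names = FALSE)
  invisible(x)
}
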