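# Independent brute-force oracles used to cross-check the exact engines.
# These deliberately recompute probabilities by naive recursion/enumeration
# in plain doubles, not through the package's distribution machinery.

# Marker-retention distribution by exhaustive depth-first recursion over the
# event graph: P(class) = mean over available events of P(class | event).
oracle_marker_products <- function(con) {
  ev <- enumerate_events(con)
  lab <- paste(intersect(c("mCe", "mO", "mC"), construct_markers(con)),
               collapse = "+")
  if (nrow(ev) == 0L) return(stats::setNames(1, lab))
  acc <- numeric(0)
  for (k in seq_len(nrow(ev))) {
    sub <- oracle_marker_products(apply_event(con, ev[k, ]))
    for (i in seq_along(sub)) {
      nm <- names(sub)[i]
      j <- match(nm, names(acc))
      if (is.na(j)) {
        acc <- c(acc, stats::setNames(sub[[i]] / nrow(ev), nm))
      } else {
        acc[j] <- acc[j] + sub[[i]] / nrow(ev)
      }
    }
  }
  acc
}

# Phenotype-class distribution of a single-autosomal-locus cross by direct
# enumeration of (maternal allele, paternal allele, resolution) triples.
# Allele descriptors: list(markers=<chr>, resolvable=<lgl>, mO=<name>,
# mC=<name>). Returns a named numeric vector over class labels.
oracle_single_locus_cross <- function(mother_alleles, father_alleles,
                                      alleles, p, b,
                                      cre_mother = FALSE, cre_father = FALSE) {
  resolve <- function(a_name, cre) {
    a <- alleles[[a_name]]
    if (!cre || !isTRUE(a$resolvable)) {
      return(list(list(name = a_name, w = 1)))
    }
    list(list(name = a_name, w = 1 - p),
         list(name = a$mO, w = p * b),
         list(name = a$mC, w = p * (1 - b)))
  }
  out <- numeric(0)
  add <- function(lab, w) {
    j <- match(lab, names(out))
    if (is.na(j)) out <<- c(out, stats::setNames(w, lab)) else out[j] <<- out[j] + w
  }
  for (ma in mother_alleles) {
    for (fa in father_alleles) {
      for (mr in resolve(ma, cre_mother)) {
        for (fr in resolve(fa, cre_father)) {
          mk <- union(alleles[[mr$name]]$markers, alleles[[fr$name]]$markers)
          lab <- paste(intersect(c("mCe", "mO", "mC"), mk), collapse = "+")
          add(lab, (1 / length(mother_alleles)) * (1 / length(father_alleles)) *
                mr$w * fr$w)
        }
      }
    }
  }
  out[out > 0]
}

# textbook one-sample t-test
oracle_ttest <- function(x, mu) {
  n <- length(x)
  t <- (mean(x) - mu) / (stats::sd(x) / sqrt(n))
  list(statistic = t, p_value = 2 * stats::pt(-abs(t), n - 1))
}

# convenience: exact pmf -> named numeric vector
pmf_as_vector <- function(x) {
  stats::setNames(as.numeric(x$probs), x$labels)
}

# probability of one label as numeric, empty-name safe
pvec <- function(v, label) {
  j <- match(label, names(v))
  if (is.na(j)) 0 else unname(v[j])
}
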