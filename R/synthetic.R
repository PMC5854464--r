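#' Synthetic brood-score generation
#'
#' Stochastic counterpart of the exact plan runner: broods are multinomial
#' draws from each step's exact offspring distribution, and the parents of
#' the next step are sampled from the realized brood of the selected
#' phenotype class. The generator emulates the shape of a mating-procedure
#' result table -- per-subline, per-step counts over the eight phenotype
#' classes -- so every downstream statistic can be exercised without any
#' external data.
#'
#' @name synthetic_data
NULL

#' Multinomial draw of one brood
#'
#' @param dist class distribution: a [pmf()] or a named numeric vector of
#'   probabilities summing to 1.
#' @param n brood size (non-negative integer).
#' @param seed optional seed; when supplied the draw is a pure function of
#'   `(dist, n, seed)`, otherwise the current RNG stream is used.
#' @return named integer vector of class counts summing to `n`.
#' @export
sample_brood <- function(dist, n, seed = NULL) {
  if (inherits(dist, "pmf")) {
    labels <- dist$labels
    probs <- as.numeric(dist$probs)
    if (pmf_total(dist) != rational(1)) {
      stop("brood distribution must sum to 1", call. = FALSE)
    }
  } else {
    if (is.null(names(dist))) stop("dist must be named", call. = FALSE)
    labels <- names(dist)
    probs <- as.numeric(dist)
    if (any(probs < 0) || abs(sum(probs) - 1) > 1e-9) {
      stop("brood distribution must be non-negative and sum to 1",
           call. = FALSE)
    }
  }
  n <- as.integer(n)
  if (is.na(n) || n < 0L) stop("n must be a non-negative integer", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (n == 0L) return(stats::setNames(integer(length(labels)), labels))
  counts <- as.integer(stats::rmultinom(1L, n, probs))
  stats::setNames(counts, labels)
}

# deterministic per-subline seed stream: adding sublines never perturbs
# earlier ones
.subline_seed <- function(seed, i) {
  ((as.numeric(seed) %% 2147483647) + i * 1000003) %% 2147483647
}

#' Simulate a crossing plan and score the broods
#'
#' For each subline the plan is run stochastically: at every step the
#' required mother and father are sampled from the realized progeny of the
#' selected class (or taken from the external line), the brood is drawn
#' multinomially from the exact offspring distribution of that concrete
#' parent pair, and the class counts are recorded. A subline whose required
#' class has zero realized count, or whose selected parents are sterile
#' (zero-size brood), is marked aborted at that step; aborts are data, not
#' errors.
#'
#' @param plan a [crossing_plan()].
#' @param sublines number of independent sublines.
#' @param n_per_step brood sizes: a single number, a named vector/list by
#'   step id, or `NULL` to draw each brood size uniformly from 50 to 132
#'   (the range typical of the scored broods).
#' @param seed integer seed; each subline derives its own stream from it.
#' @param by_sex record counts split by offspring sex?
#' @return A score-table data frame (`step`, `subline`, optional `sex`,
#'   `class`, `count`) with attributes `aborts` (data frame `subline`,
#'   `step`) and `seed`.
#' @export
generate_score_table <- function(plan, sublines, n_per_step = NULL,
                                 seed = 1L, by_sex = FALSE) {
  stopifnot(inherits(plan, "crossing_plan"))
  sublines <- as.integer(sublines)
  exact <- run_exact(plan)   # step-level support for zero-count padding
  rows <- list()
  aborts <- list()

  brood_n <- function(id) {
    if (is.null(n_per_step)) return(sample(50:132, 1L))
    if (length(n_per_step) == 1L && is.null(names(n_per_step))) {
      return(as.integer(n_per_step))
    }
    v <- n_per_step[[id]]
    if (is.null(v)) stop(sprintf("no brood size for step '%s'", id),
                         call. = FALSE)
    as.integer(v)
  }

  for (i in seq_len(sublines)) {
    set.seed(.subline_seed(seed, i))
    subline_id <- sprintf("S%02d", i)
    stock <- list()  # step id -> list(genotypes, counts)
    for (step in plan$steps) {
      pick <- function(sel) {
        if (sel$source %in% names(plan$lines)) {
          return(plan$lines[[sel$source]])
        }
        st <- stock[[sel$source]]
        if (is.null(st)) return(NULL)
        ok <- vapply(st$genotypes, function(g) {
          g$sex == sel$sex &&
            identical(phenotype_of(g, plan$registry), sel$class)
        }, logical(1))
        total <- sum(st$counts[ok])
        if (total == 0L) return(NULL)
        idx <- which(ok)
        k <- if (length(idx) == 1L) idx else {
          sample(idx, 1L, prob = st$counts[idx])
        }
        st$genotypes[[k]]
      }
      mother <- pick(step$mother)
      father <- pick(step$father)
      if (is.null(mother) || is.null(father)) {
        aborts[[length(aborts) + 1L]] <- data.frame(
          subline = subline_id, step = step$id,
          reason = "required parent class not available",
          stringsAsFactors = FALSE)
        break
      }
      sterile <- !is.null(plan$params$fertile) &&
        (!isTRUE(plan$params$fertile(mother, plan$registry)) ||
           !isTRUE(plan$params$fertile(father, plan$registry)))
      n <- if (sterile) 0L else brood_n(step$id)
      d <- cross_exact(mother, father, plan$params, plan$registry,
                       step$cre_active_mother, step$cre_active_father)
      if (!is.null(plan$params$viable)) {
        d <- apply_viability(d, plan$params, plan$registry)
      }
      counts <- if (n == 0L) {
        integer(length(d$keys))
      } else {
        as.integer(stats::rmultinom(1L, n, as.numeric(d$probs)))
      }
      stock[[step$id]] <- list(genotypes = d$outcomes, counts = counts)

      # record class-level counts; pad classes the step could produce
      if (by_sex) {
        labels <- vapply(seq_along(d$keys), function(k) {
          paste(d$outcomes[[k]]$sex,
                phenotype_of(d$outcomes[[k]], plan$registry), sep = "|")
        }, character(1))
      } else {
        labels <- vapply(d$outcomes, phenotype_of, character(1),
                         registry = plan$registry)
      }
      agg <- tapply(counts, labels, sum)
      support <- if (by_sex) {
        exact[[step$id]]$classes_by_sex$labels
      } else {
        exact[[step$id]]$classes$labels
      }
      all_labels <- union(support, names(agg))
      cc <- stats::setNames(integer(length(all_labels)), all_labels)
      # match(), not name-indexing: the wild-type class label is ""
      cc[match(names(agg), all_labels)] <- as.integer(agg)
      row <- data.frame(step = step$id, subline = subline_id,
                        class = all_labels, count = as.integer(cc),
                        stringsAsFactors = FALSE)
      if (by_sex) {
        parts <- strsplit(row$class, "|", fixed = TRUE)
        row$sex <- vapply(parts, `[[`, character(1), 1L)
        row$class <- vapply(parts, function(p) {
          if (length(p) > 1L) p[[2L]] else ""
        }, character(1))
        row <- row[, c("step", "subline", "sex", "class", "count")]
      }
      rows[[length(rows) + 1L]] <- row
      if (sterile) {
        aborts[[length(aborts) + 1L]] <- data.frame(
          subline = subline_id, step = step$id,
          reason = "sterile parents: zero-progeny brood",
          stringsAsFactors = FALSE)
        break
      }
    }
  }

  out <- if (length(rows) == 0L) {
    data.frame(step = character(0), subline = character(0),
               class = character(0), count = integer(0),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, rows)
  }
  rownames(out) <- NULL
  attr(out, "aborts") <- if (length(aborts) == 0L) {
    data.frame(subline = character(0), step = character(0),
               reason = character(0), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, aborts)
  }
  attr(out, "seed") <- seed
  out
}
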