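#' Multi-generation crossing plans
#'
#' A crossing plan encodes a mating procedure as data: external lines
#' (named genotypes), an ordered list of steps, and germline parameters.
#' Each step selects a mother and a father -- from an external line or, by
#' phenotype class and sex, from an earlier step's progeny -- and records the
#' cross. Selecting by phenotype averages over the genotypes hidden within
#' the class, weighted by their exact conditional probabilities; this is
#' what a researcher selecting individuals by eye marker actually does, and
#' it is what makes the trans-configuration control cross informative.
#'
#' @name scheme
NULL

#' Parent selector for a plan step
#'
#' @param source name of an external line or the id of an earlier step.
#' @param class phenotype class to select (required when `source` is a
#'   step; checked against the line's phenotype when given for a line).
#' @param sex `"female"` or `"male"`.
#' @return A `selector`.
#' @export
selector <- function(source, class = NULL, sex = c("female", "male")) {
  sex <- match.arg(sex)
  structure(list(source = source, class = class, sex = sex),
            class = "selector")
}

#' One step of a crossing plan
#'
#' @param id step label (e.g. `"F3"`, `"F6-S"`). By convention the label is
#'   the parents' generation; the step's distribution describes their
#'   progeny.
#' @param mother,father [selector()]s (mother female, father male).
#' @param cre_active_mother,cre_active_father override automatic germline
#'   Cre activation for this step.
#' @return A `plan_step`.
#' @export
plan_step <- function(id, mother, father,
                      cre_active_mother = NULL, cre_active_father = NULL) {
  stopifnot(inherits(mother, "selector"), inherits(father, "selector"))
  if (mother$sex != "female") stop("mother selector must be female", call. = FALSE)
  if (father$sex != "male") stop("father selector must be male", call. = FALSE)
  structure(list(id = id, mother = mother, father = father,
                 cre_active_mother = cre_active_mother,
                 cre_active_father = cre_active_father),
            class = "plan_step")
}

#' Assemble a crossing plan
#'
#' @param name plan label.
#' @param lines named list of external-line [genotype()]s.
#' @param steps list of [plan_step()]s, ordered; selectors may reference
#'   lines or earlier steps only.
#' @param params [sim_params()].
#' @param registry allele registry.
#' @return A `crossing_plan`.
#' @export
crossing_plan <- function(name, lines, steps, params = sim_params(),
                          registry = standard_alleles()) {
  stopifnot(is.list(lines), is.list(steps))
  if (length(steps) == 0L) stop("plan needs at least one step", call. = FALSE)
  ids <- vapply(steps, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("duplicate step ids", call. = FALSE)
  structure(list(name = name, lines = lines, steps = steps,
                 params = params, registry = registry),
            class = "crossing_plan")
}

#' @export
format.crossing_plan <- function(x, ...) {
  sprintf("<crossing_plan %s: %d line(s), %d step(s), p=%s, b=%s>",
          x$name, length(x$lines), length(x$steps),
          format(x$params$p), format(x$params$b))
}

#' @export
print.crossing_plan <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

.step_ids <- function(plan) vapply(plan$steps, `[[`, character(1), "id")

# Resolve a selector into a genotype distribution, given results so far.
.resolve_parent <- function(plan, sel, results) {
  if (sel$source %in% names(plan$lines)) {
    g <- plan$lines[[sel$source]]
    if (g$sex != sel$sex) {
      stop(sprintf("line '%s' is %s but selector requires %s",
                   sel$source, g$sex, sel$sex), call. = FALSE)
    }
    if (!is.null(sel$class)) {
      actual <- phenotype_of(g, plan$registry)
      if (!identical(actual, sel$class)) {
        stop(sprintf("line '%s' has phenotype class '%s', selector asks '%s'",
                     sel$source, actual, sel$class), call. = FALSE)
      }
    }
    return(.gdist(list(g), rational(1), genotype_key(g)))
  }
  if (!sel$source %in% names(results)) {
    stop(sprintf("selector references unknown source '%s'", sel$source),
         call. = FALSE)
  }
  if (is.null(sel$class)) {
    stop(sprintf("selecting from step '%s' requires a phenotype class",
                 sel$source), call. = FALSE)
  }
  d <- results[[sel$source]]$offspring
  keep <- vapply(d$outcomes, function(g) {
    g$sex == sel$sex && identical(phenotype_of(g, plan$registry), sel$class)
  }, logical(1))
  if (!any(keep) || as.numeric(sum(d$probs[keep])) == 0) {
    stop(sprintf(
      "unreachable selector: class '%s' (%s) has zero probability in step '%s' progeny",
      sel$class, sel$sex, sel$source), call. = FALSE)
  }
  total <- sum(d$probs[keep])
  .gdist(d$outcomes[keep], d$probs[keep] / total, d$keys[keep])
}

# Offspring distribution of a cross between two genotype distributions:
# mother and father are drawn independently.
.cross_mixture <- function(md, fd, params, registry,
                           cre_active_mother = NULL, cre_active_father = NULL) {
  outcomes <- list(); probs <- list(); keys <- character(0)
  resolved <- FALSE
  for (i in seq_along(md$keys)) {
    for (j in seq_along(fd$keys)) {
      w <- md$probs[i] * fd$probs[j]
      d <- cross_exact(md$outcomes[[i]], fd$outcomes[[j]], params, registry,
                       cre_active_mother, cre_active_father)
      for (k in seq_along(d$keys)) {
        outcomes[[length(outcomes) + 1L]] <- d$outcomes[[k]]
        probs[[length(probs) + 1L]] <- w * d$probs[k]
        keys <- c(keys, d$keys[k])
      }
      for (par in list(md$outcomes[[i]], fd$outcomes[[j]])) {
        if (carries_cre(par, registry) &&
            any(vapply(unlist(lapply(par$loci, `[[`, "alleles")),
                       function(a) .get_allele(registry, a)$resolvable,
                       logical(1)))) {
          resolved <- TRUE
        }
      }
    }
  }
  out <- .gdist_merge(outcomes, do.call(c.rational, probs), keys)
  attr(out, "resolved") <- resolved
  out
}

#' Validate a crossing plan
#'
#' Checks that selectors reference declared lines or earlier steps only and
#' that every selected phenotype class has positive probability under exact
#' enumeration (by incrementally running the plan). Findings are returned,
#' not thrown.
#'
#' @param plan a [crossing_plan()].
#' @return data frame of findings (`level`, `step`, `message`); zero rows
#'   when the plan is clean.
#' @export
validate_plan <- function(plan) {
  stopifnot(inherits(plan, "crossing_plan"))
  findings <- list()
  add <- function(level, step, message) {
    findings[[length(findings) + 1L]] <<- data.frame(
      level = level, step = step, message = message, stringsAsFactors = FALSE)
  }
  ids <- .step_ids(plan)
  results <- list()
  for (s in seq_along(plan$steps)) {
    step <- plan$steps[[s]]
    for (which_par in c("mother", "father")) {
      sel <- step[[which_par]]
      if (!sel$source %in% names(plan$lines) &&
          !sel$source %in% ids[seq_len(s - 1L)]) {
        add("error", step$id,
            sprintf("%s selector references '%s', which is not a line or an earlier step",
                    which_par, sel$source))
      }
    }
    res <- tryCatch(
      .run_step(plan, step, results),
      error = function(e) {
        add("error", step$id, conditionMessage(e))
        NULL
      })
    if (is.null(res)) break
    results[[step$id]] <- res
  }
  if (length(findings) == 0L) {
    return(data.frame(level = character(0), step = character(0),
                      message = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, findings)
}

.run_step <- function(plan, step, results) {
  md <- .resolve_parent(plan, step$mother, results)
  fd <- .resolve_parent(plan, step$father, results)
  offspring <- .cross_mixture(md, fd, plan$params, plan$registry,
                              step$cre_active_mother, step$cre_active_father)
  list(id = step$id,
       mother = md, father = fd,
       offspring = offspring,
       classes = class_distribution(offspring, plan$registry),
       classes_by_sex = class_distribution(offspring, plan$registry,
                                           by_sex = TRUE),
       resolved = isTRUE(attr(offspring, "resolved")))
}

#' Run a crossing plan exactly
#'
#' For every step, the exact offspring distribution of the cross defined by
#' its selectors, conditioned on the selected parental phenotype class
#' (weighting hidden genotypes by their conditional probability within the
#' class).
#'
#' @param plan a [crossing_plan()].
#' @return A `plan_result`: named list (by step id) of lists with
#'   `offspring` (genotype distribution), `classes` ([pmf()] over phenotype
#'   classes), `classes_by_sex`, and `resolved` (did germline Cre resolution
#'   occur in this step's parents?).
#' @export
run_exact <- function(plan) {
  stopifnot(inherits(plan, "crossing_plan"))
  results <- list()
  for (step in plan$steps) {
    results[[step$id]] <- .run_step(plan, step, results)
  }
  structure(results, class = "plan_result")
}

#' Tabulate a plan result as theoretical class percentages
#'
#' @param res a `plan_result` from [run_exact()].
#' @param by_sex include the sex-split distributions?
#' @return data frame with columns `step`, `class`, `fraction`,
#'   `percent` (plus `sex` when `by_sex = TRUE`).
#' @export
theoretical_table <- function(res, by_sex = FALSE) {
  rows <- lapply(names(res), function(id) {
    cd <- if (by_sex) res[[id]]$classes_by_sex else res[[id]]$classes
    df <- as.data.frame(cd)
    if (by_sex) {
      parts <- strsplit(df$label, "|", fixed = TRUE)
      df$sex <- vapply(parts, `[[`, character(1), 1L)
      df$class <- vapply(parts, function(p) {
        if (length(p) > 1L) p[[2L]] else ""
      }, character(1))
    } else {
      df$class <- df$label
    }
    df$step <- id
    df
  })
  out <- do.call(rbind, rows)
  cols <- c("step", if (by_sex) "sex", "class", "fraction", "percent")
  out <- out[, cols]
  rownames(out) <- NULL
  out
}

# ---- diagnosis ------------------------------------------------------------

#' Diagnose special cases of transgenesis from observed scores
#'
#' Compares an observed [score table][read_score_table()] against a plan's
#' exact expectations and flags:
#' \describe{
#'   \item{incomplete_recombination}{residual both-marker classes in a
#'     post-recombination step where the plan expects none; the germline
#'     resolution efficiency is estimated as
#'     1 - both-marker carriers / transgene carriers, with a
#'     Clopper-Pearson interval.}
#'   \item{suspected_lethality}{an expected class absent although, at the
#'     step's theoretical rate and pooled brood size, absence is
#'     improbable (exact binomial test).}
#'   \item{sterility}{zero-progeny broods replicated at one step (at least
#'     `min_sterile_replicates` pairs, default 8, matching the replication
#'     used to call a line sterile).}
#'   \item{x_linkage}{marker presence associated with offspring sex
#'     (Fisher's exact test; only evaluated when the table records sex).}
#' }
#'
#' @param scores score table (`step`, `subline`, optional `sex`, `class`,
#'   `count`).
#' @param plan the [crossing_plan()] the scores came from.
#' @param alpha significance level for the lethality and X-linkage tests.
#' @param min_sterile_replicates zero-progeny pairs required to flag
#'   sterility.
#' @return A `diagnosis_report`: list of flags, each carrying the counts
#'   that triggered it.
#' @export
diagnose_scores <- function(scores, plan, alpha = 0.05,
                            min_sterile_replicates = 8L) {
  if (is.null(scores) || nrow(scores) == 0L) {
    stop("empty score table", call. = FALSE)
  }
  res <- run_exact(plan)
  flags <- list()

  # incomplete recombination: post-recombination steps only
  post_steps <- names(res)[vapply(res, `[[`, logical(1), "resolved")]
  for (id in intersect(post_steps, unique(scores$step))) {
    est <- tryCatch(
      estimate_recombination_efficiency(scores, id),
      error = function(e) NULL)
    if (!is.null(est) && est$both > 0L) {
      theo_both <- sum(vapply(res[[id]]$classes$labels, function(cl) {
        if (.has_both_markers(cl)) as.numeric(pmf_prob(res[[id]]$classes, cl))
        else 0
      }, numeric(1)))
      if (theo_both == 0) {
        flags$incomplete_recombination <- c(list(step = id), est)
      }
    }
  }

  # suspected lethality: expected class absent at adequate n
  leth <- list()
  for (id in intersect(names(res), unique(scores$step))) {
    rows <- scores[scores$step == id, , drop = FALSE]
    n <- sum(rows$count)
    if (n == 0L) next
    for (k in seq_along(res[[id]]$classes$labels)) {
      cl <- res[[id]]$classes$labels[k]
      q <- as.numeric(res[[id]]$classes$probs[k])
      if (q <= 0) next
      obs <- sum(rows$count[rows$class == cl])
      if (obs == 0L) {
        p_absent <- (1 - q)^n
        if (p_absent < alpha) {
          leth[[length(leth) + 1L]] <- data.frame(
            step = id, class = cl, n = n, theoretical = q,
            p_absent = p_absent, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(leth) > 0L) flags$suspected_lethality <- do.call(rbind, leth)

  # sterility: replicated zero-progeny broods
  grp <- stats::aggregate(count ~ step + subline, data = scores, FUN = sum)
  zero <- grp[grp$count == 0L, , drop = FALSE]
  if (nrow(zero) > 0L) {
    tab <- table(zero$step)
    hit <- names(tab)[tab >= min_sterile_replicates]
    if (length(hit) > 0L) {
      flags$sterility <- data.frame(step = hit,
                                    n_zero_broods = as.integer(tab[hit]),
                                    stringsAsFactors = FALSE)
    }
  }

  # X linkage: sex-biased marker segregation (needs a sex column)
  if ("sex" %in% names(scores)) {
    # one Fisher test per (step, marker); Bonferroni within the family so a
    # run over many steps does not raise spurious linkage flags
    xl <- list()
    for (id in unique(scores$step)) {
      rows <- scores[scores$step == id, , drop = FALSE]
      for (m in .MARKER_ORDER) {
        has_m <- .class_has_marker(rows$class, m)
        tab <- rbind(
          female = c(sum(rows$count[has_m & rows$sex == "female"]),
                     sum(rows$count[!has_m & rows$sex == "female"])),
          male = c(sum(rows$count[has_m & rows$sex == "male"]),
                   sum(rows$count[!has_m & rows$sex == "male"])))
        if (any(rowSums(tab) == 0L) || sum(tab[, 1]) == 0L) next
        pv <- stats::fisher.test(tab)$p.value
        xl[[length(xl) + 1L]] <- data.frame(
          step = id, marker = m, p_value = pv,
          carrier_female = tab["female", 1], noncarrier_female = tab["female", 2],
          carrier_male = tab["male", 1], noncarrier_male = tab["male", 2],
          stringsAsFactors = FALSE)
      }
    }
    if (length(xl) > 0L) {
      xl <- do.call(rbind, xl)
      hit <- xl[xl$p_value < alpha / nrow(xl), , drop = FALSE]
      if (nrow(hit) > 0L) flags$x_linkage <- hit
    }
  }

  structure(flags, class = "diagnosis_report")
}

.class_has_marker <- function(class, marker) {
  vapply(strsplit(class, "+", fixed = TRUE),
         function(parts) marker %in% parts, logical(1))
}

.has_both_markers <- function(class) {
  .class_has_marker(class, "mO") & .class_has_marker(class, "mC")
}

.is_carrier_class <- function(class) {
  .class_has_marker(class, "mO") | .class_has_marker(class, "mC")
}

#' @export
print.diagnosis_report <- function(x, ...) {
  if (length(x) == 0L) {
    cat("<diagnosis_report: no flags>\n")
    return(invisible(x))
  }
  cat("<diagnosis_report>\n")
  for (nm in names(x)) {
    cat("--", nm, "--\n")
    if (is.data.frame(x[[nm]])) {
      print(x[[nm]], row.names = FALSE)
    } else {
      utils::str(x[[nm]], give.attr = FALSE)
    }
  }
  invisible(x)
}
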