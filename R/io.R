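#' Score-table and configuration I/O
#'
#' Score tables are tab-delimited UTF-8 text with Unix newlines and header
#' `step  subline  [sex]  class  count`; classes use the canonical labels of
#' [phenotype_classes()]. Plans and constructs are YAML. Exact fractions are
#' rendered as `"a/b"` alongside percentages in report output.
#'
#' @name io
NULL

#' Read a score table
#'
#' @param path TSV file with header `step`, `subline`, optional `sex`,
#'   `class`, `count`.
#' @return validated score-table data frame.
#' @export
read_score_table <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) stop("empty score-table file", call. = FALSE)
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  has_sex <- identical(header, c("step", "subline", "sex", "class", "count"))
  if (!has_sex &&
      !identical(header, c("step", "subline", "class", "count"))) {
    stop("score-table header must be 'step subline [sex] class count' (tab-separated)",
         call. = FALSE)
  }
  ncol <- length(header)
  rows <- vector("list", length(lines) - 1L)
  for (ln in seq_along(lines)[-1L]) {
    line <- lines[[ln]]
    if (line == "") next
    f <- strsplit(line, "\t", fixed = TRUE)[[1L]]
    if (length(f) != ncol) {
      stop(sprintf("line %d: expected %d fields, got %d", ln, ncol, length(f)),
           call. = FALSE)
    }
    cl <- f[[ncol - 1L]]
    if (!cl %in% phenotype_classes()) {
      stop(sprintf("line %d: unknown phenotype class '%s'", ln, cl),
           call. = FALSE)
    }
    cnt <- suppressWarnings(as.numeric(f[[ncol]]))
    if (is.na(cnt) || cnt != trunc(cnt)) {
      stop(sprintf("line %d: count '%s' is not an integer", ln, f[[ncol]]),
           call. = FALSE)
    }
    if (cnt < 0) {
      stop(sprintf("line %d: negative count", ln), call. = FALSE)
    }
    if (has_sex && !f[[3L]] %in% c("female", "male")) {
      stop(sprintf("line %d: sex must be 'female' or 'male'", ln),
           call. = FALSE)
    }
    rows[[ln - 1L]] <- f
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    out <- data.frame(step = character(0), subline = character(0),
                      class = character(0), count = integer(0),
                      stringsAsFactors = FALSE)
    if (has_sex) out$sex <- character(0)
    return(out[, header])
  }
  m <- do.call(rbind, rows)
  out <- data.frame(m, stringsAsFactors = FALSE)
  names(out) <- header
  out$count <- as.integer(out$count)
  # within a (step, subline[, sex]) group, classes must be distinct
  grp_cols <- setdiff(header, c("class", "count"))
  key <- do.call(paste, c(out[grp_cols], list(out$class, sep = "\r")))
  if (anyDuplicated(key)) {
    stop("duplicate class within a (step, subline) group", call. = FALSE)
  }
  out
}

#' @rdname read_score_table
#' @param scores score-table data frame.
#' @export
write_score_table <- function(scores, path) {
  cols <- intersect(c("step", "subline", "sex", "class", "count"),
                    names(scores))
  utils::write.table(scores[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}

# ---- plan configuration ---------------------------------------------------

.registry_from_config <- function(alleles_cfg) {
  reg <- lapply(names(alleles_cfg), function(nm) {
    a <- alleles_cfg[[nm]]
    make_allele(nm,
                markers = unlist(a$markers) %||% character(0),
                cre = isTRUE(a$cre),
                resolved_mO = a$resolved_mO %||% NA_character_,
                resolved_mC = a$resolved_mC %||% NA_character_)
  })
  stats::setNames(reg, names(alleles_cfg))
}

#' Read a crossing-plan configuration
#'
#' YAML with fields `name`, `params` (`p`, `b` as numbers or `"a/b"`
#' strings), `alleles` (name -> markers / cre / resolution products),
#' `loci` (locus -> chromosome), `lines` (name -> sex + per-locus allele
#' names) and ordered `steps` (id, mother/father selectors with `source`,
#' optional `class`, `sex`).
#'
#' @param path YAML file.
#' @return A [crossing_plan()].
#' @export
read_plan_config <- function(path) {
  doc <- yaml::read_yaml(path)
  registry <- .registry_from_config(doc$alleles)
  loci_map <- doc$loci
  lines <- lapply(doc$lines, function(l) {
    loci <- lapply(names(l$alleles), function(nm) {
      locus(loci_map[[nm]], unlist(l$alleles[[nm]]))
    })
    genotype(l$sex, loci = stats::setNames(loci, names(l$alleles)))
  })
  steps <- lapply(doc$steps, function(s) {
    mk_sel <- function(sl, sex_default) {
      selector(sl$source, class = sl$class, sex = sl$sex %||% sex_default)
    }
    plan_step(s$id,
              mother = mk_sel(s$mother, "female"),
              father = mk_sel(s$father, "male"),
              cre_active_mother = s$cre_active_mother,
              cre_active_father = s$cre_active_father)
  })
  params <- sim_params(p = as_rational(doc$params$p %||% 1),
                       b = as_rational(doc$params$b %||% "1/2"))
  crossing_plan(doc$name, lines, steps, params, registry)
}

# ---- bundled data ---------------------------------------------------------

#' Path to a bundled data file
#' @param name file name under the package's `extdata`.
#' @return file path.
#' @export
bundled_file <- function(name) {
  path <- system.file("extdata", name, package = "loxcross", mustWork = FALSE)
  if (path == "") stop(sprintf("no bundled file '%s'", name), call. = FALSE)
  path
}

#' Bundled crossing plans
#'
#' `"canonical"`: the F3-to-F7 homozygosity procedure on two independent
#' autosomes. `"swapped"`: the same procedure with parental genders
#' exchanged at every step. `"xlinked"`: the variant for a transgene on the
#' X chromosome, reconstructed by enumeration (transgenic males are
#' hemizygous X-carriers, so homozygosity is reached in females first).
#'
#' @param which plan name.
#' @return A [crossing_plan()].
#' @export
bundled_plan <- function(which = c("canonical", "swapped", "xlinked")) {
  which <- match.arg(which)
  read_plan_config(bundled_file(sprintf("plan_%s.yaml", which)))
}

#' Bundled constructs
#'
#' The canonical dual-marker interweaved-Lox construct, the Cre-helper
#' marker cassette, and the tandem-duplicated (nested-insertion) construct.
#' @return named list of `construct`s.
#' @export
bundled_constructs <- function() {
  read_construct_config(bundled_file("constructs.yaml"))
}

#' Transcribed mating-procedure result counts
#'
#' The published per-subline progeny counts of the six proof-of-principle
#' sublines across the seven scored crosses (F3, F4, F5, F6-S, F6, F7-O,
#' F7-C), transcribed from the printed result table. Two transcription
#' corrections reconcile internally inconsistent printed cells: the F6-S
#' subline-1 mC count is stored as 45 (printed "44" contradicts both the
#' printed total of 84 and the printed percentage 53.6%), and the F6
#' subline-2 total is the count sum 107 (the printed total 117 contradicts
#' the printed counts and percentages).
#'
#' @return score-table data frame (7 steps x 6 sublines).
#' @export
table1_scores <- function() {
  read_score_table(bundled_file("table1_scores.tsv"))
}

#' Reproduce the published result-table summary from bundled data
#'
#' Recomputes, from the bundled transcribed counts and the bundled
#' canonical plan, the theoretical class percentages and the across-subline
#' mean +/- SD rows, in one tidy table.
#'
#' @return data frame `step`, `class`, `theoretical_pct`, `fraction`,
#'   `mean_pct`, `sd_pct`, `statistic`, `df`, `p_value`.
#' @export
reproduce_table1 <- function() {
  plan <- bundled_plan("canonical")
  res <- run_exact(plan)
  scores <- table1_scores()
  summary <- summarize_scores(scores, theoretical = res)
  theo <- theoretical_table(res)
  out <- merge(summary, theo[, c("step", "class", "fraction")],
               by = c("step", "class"), all.x = TRUE)
  out <- out[, c("step", "class", "theoretical_pct", "fraction",
                 "n_sublines", "mean_pct", "sd_pct", "statistic", "df",
                 "p_value")]
  out <- out[order(match(out$step, names(res)),
                   match(out$class, phenotype_classes())), ]
  rownames(out) <- NULL
  out
}
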