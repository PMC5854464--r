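canonical <- bundled_plan("canonical")

test_that("the bundled plans validate cleanly", {
  expect_equal(nrow(validate_plan(canonical)), 0L)
  expect_equal(nrow(validate_plan(bundled_plan("swapped"))), 0L)
  expect_equal(nrow(validate_plan(bundled_plan("xlinked"))), 0L)
})

test_that("unreachable selectors are reported with the offending step", {
  bad <- crossing_plan(
    "bad", canonical$lines,
    list(plan_step("W", selector("wt_female"), selector("wt_male", sex = "male")),
         plan_step("X", selector("W", class = "mO+mC"),
                   selector("wt_male", sex = "male"))),
    canonical$params, canonical$registry)
  v <- validate_plan(bad)
  expect_true(any(v$level == "error" & v$step == "X" &
                    grepl("unreachable|zero probability", v$message)))
  fwd <- crossing_plan(
    "fwd", canonical$lines,
    list(plan_step("A", selector("Z", class = "mO"),
                   selector("wt_male", sex = "male"))),
    canonical$params, canonical$registry)
  v2 <- validate_plan(fwd)
  expect_true(any(grepl("not a line or an earlier step", v2$message)))
})

test_that("the exact run reproduces every theoretical ratio of the procedure", {
  res <- run_exact(canonical)
  want <- list(
    "F3"   = list("mCe" = c(1, 2), "mCe+mO+mC" = c(1, 2)),
    "F4"   = setNames(list(c(1, 4), c(1, 4), c(1, 8), c(1, 8), c(1, 8), c(1, 8)),
                      c("", "mCe", "mO", "mC", "mCe+mO", "mCe+mC")),
    "F5"   = setNames(list(c(1, 4), c(1, 4), c(1, 4), c(1, 4)),
                      c("", "mO", "mC", "mO+mC")),
    "F6-S" = list("mO" = c(1, 2), "mC" = c(1, 2)),
    "F6"   = list("mO" = c(1, 4), "mC" = c(1, 4), "mO+mC" = c(1, 2)),
    "F7-O" = list("mO" = c(1, 1)),
    "F7-C" = list("mC" = c(1, 1)))
  for (id in names(want)) {
    cd <- res[[id]]$classes
    expect_true(pmf_total(cd) == rational(1))
    expect_equal(length(cd), length(want[[id]]))
    for (k in seq_along(want[[id]])) {
      lab <- names(want[[id]])[k]
      v <- want[[id]][[k]]
      expect_true(pmf_prob(cd, lab) == rational(v[1], v[2]),
                  label = sprintf("step %s class '%s'", id, lab))
    }
  }
  # the trans-configuration control has no wild-type progeny
  expect_true(pmf_prob(res[["F6-S"]]$classes, "") == rational(0))
})

test_that("the swapped-gender plan yields identical class distributions", {
  res_c <- run_exact(canonical)
  res_s <- run_exact(bundled_plan("swapped"))
  for (id in names(res_c)) {
    a <- res_c[[id]]$classes
    b <- res_s[[id]]$classes
    expect_setequal(a$labels, b$labels)
    for (lab in a$labels) {
      expect_true(pmf_prob(a, lab) == pmf_prob(b, lab),
                  label = sprintf("step %s class '%s'", id, lab))
    }
  }
})

test_that("cis and trans both-marker parents are distinguished by the test cross", {
  reg <- canonical$registry
  lines <- list(
    cis_female = genotype("female",
                          dm = locus("autosome-1", c("DM-full", "WT")),
                          helper = locus("autosome-2", c("WT", "WT"))),
    trans_female = genotype("female",
                            dm = locus("autosome-1", c("DM-mO", "DM-mC")),
                            helper = locus("autosome-2", c("WT", "WT"))),
    wt_male = canonical$lines$wt_male)
  mk <- function(src) crossing_plan(
    "probe", lines,
    list(plan_step("S", selector(src, class = "mO+mC"),
                   selector("wt_male", sex = "male"))),
    sim_params(), reg)
  cis <- run_exact(mk("cis_female"))[["S"]]$classes
  trans <- run_exact(mk("trans_female"))[["S"]]$classes
  # cis: half the progeny are wild type; trans: none are
  expect_true(pmf_prob(cis, "") == rational(1, 2))
  expect_true(pmf_prob(cis, "mO+mC") == rational(1, 2))
  expect_true(pmf_prob(trans, "") == rational(0))
  expect_true(pmf_prob(trans, "mO") == rational(1, 2))
})

test_that("the X-linked plan reaches homozygosity and keeps sons transgene-free", {
  xl <- bundled_plan("xlinked")
  res <- run_exact(xl)
  # F7 control crosses: 100% single-marker progeny of both sexes
  expect_true(pmf_prob(res[["F7-O"]]$classes, "mO") == rational(1))
  expect_true(pmf_prob(res[["F7-C"]]$classes, "mC") == rational(1))
  # in the F5 step the father carries mC on his X: no son displays mC
  f5 <- res[["F5"]]$classes_by_sex
  for (lab in f5$labels) {
    if (startsWith(lab, "male|")) {
      expect_false(grepl("mC", sub("male\\|", "", lab)))
    }
  }
})

test_that("phenotype selection weights hidden genotypes correctly at p < 1", {
  # with partial resolution the both-marker class of the post-recombination
  # generation mixes residual cis alleles and (later) trans heterozygotes;
  # downstream ratios must reflect the exact conditional mix
  plan <- crossing_plan(
    canonical$name, canonical$lines,
    canonical$steps[1:3],           # F3, F4, F5
    sim_params(p = "9/10", b = "1/2"), canonical$registry)
  res <- run_exact(plan)
  f4 <- res[["F4"]]$classes
  expect_true(pmf_prob(f4, "mO+mC") == rational(1, 40))
  expect_true(pmf_prob(f4, "mCe+mO+mC") == rational(1, 40))
  expect_true(pmf_total(f4) == rational(1))
})

test_that("diagnosis flags incomplete recombination from residual both-marker progeny", {
  t1 <- table1_scores()
  d <- diagnose_scores(t1[t1$subline == "S4", ], canonical)
  expect_true(!is.null(d$incomplete_recombination))
  expect_equal(d$incomplete_recombination$step, "F4")
  expect_equal(d$incomplete_recombination$both, 7L)
  expect_equal(d$incomplete_recombination$carriers, 71L)
  expect_equal(d$incomplete_recombination$p_hat, 1 - 7 / 71, tolerance = 1e-12)
  expect_equal(d$incomplete_recombination$residual_both_fraction, 0.07,
               tolerance = 1e-12)
})

test_that("diagnosis flags replicated zero-progeny broods as sterility", {
  rows <- do.call(rbind, lapply(1:12, function(i) {
    data.frame(step = "F6", subline = sprintf("P%02d", i),
               class = c("mO", "mC", "mO+mC"), count = 0L,
               stringsAsFactors = FALSE)
  }))
  base <- table1_scores()
  d <- suppressWarnings(
    diagnose_scores(rbind(base[base$step != "F6", ], rows), canonical))
  expect_true(!is.null(d$sterility))
  expect_equal(d$sterility$step, "F6")
  expect_equal(d$sterility$n_zero_broods, 12L)
  # fewer than the replication threshold: not flagged
  d2 <- suppressWarnings(
    diagnose_scores(rbind(base[base$step != "F6", ], rows[1:9, ]), canonical))
  expect_null(d2$sterility)
})

test_that("diagnosis flags a missing expected class as suspected lethality", {
  t1 <- table1_scores()
  drop_homo <- t1[!(t1$step == "F6" & t1$class == "mO"), ]
  d <- diagnose_scores(drop_homo, canonical)
  expect_true(!is.null(d$suspected_lethality))
  expect_true(any(d$suspected_lethality$step == "F6" &
                    d$suspected_lethality$class == "mO"))
})

test_that("a clean complete-resolution table raises no flags", {
  tbl <- generate_score_table(canonical, sublines = 6, n_per_step = 120,
                              seed = 99)
  d <- diagnose_scores(tbl, canonical)
  expect_equal(length(d), 0L)
  expect_error(diagnose_scores(tbl[0, ], canonical), "empty")
})

test_that("sex-recorded scores from an X-linked plan flag X linkage", {
  xl <- bundled_plan("xlinked")
  tbl <- generate_score_table(xl, sublines = 4, n_per_step = 120, seed = 5,
                              by_sex = TRUE)
  d <- diagnose_scores(tbl, xl)
  expect_true(!is.null(d$x_linkage))
  # autosomal plan with sex recorded: no linkage flag expected
  tbl_a <- generate_score_table(canonical, sublines = 4, n_per_step = 120,
                                seed = 5, by_sex = TRUE)
  d_a <- diagnose_scores(tbl_a, canonical)
  expect_null(d_a$x_linkage)
})
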