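reg <- standard_alleles()

dm_locus <- function(a, b = NULL) {
  locus("autosome-1", c(a, b))
}

two_locus <- function(sex, dm, helper) {
  genotype(sex, dm = locus("autosome-1", dm), helper = locus("autosome-2", helper))
}

test_that("gamete distribution resolves the full allele in a Cre germline", {
  mom <- two_locus("female", c("DM-full", "WT"), c("HELPER-mCe", "WT"))
  gd <- gamete_distribution(mom, sim_params(p = 1, b = "1/2"), reg)
  # marginal at the transgene locus: WT 1/2, resolved mO 1/4, resolved mC 1/4
  marginal <- function(gd, allele) {
    idx <- vapply(gd$outcomes, function(h) identical(h$alleles$dm, allele),
                  logical(1))
    if (!any(idx)) rational(0) else sum(gd$probs[idx])
  }
  expect_true(marginal(gd, "WT") == rational(1, 2))
  expect_true(marginal(gd, "DM-mO") == rational(1, 4))
  expect_true(marginal(gd, "DM-mC") == rational(1, 4))
  expect_true(marginal(gd, "DM-full") == rational(0))
})

test_that("partial germline resolution leaves the expected residual", {
  mom <- two_locus("female", c("DM-full", "WT"), c("HELPER-mCe", "WT"))
  gd <- gamete_distribution(mom, sim_params(p = "9/10", b = "1/2"), reg)
  marginal <- function(allele) {
    idx <- vapply(gd$outcomes, function(h) identical(h$alleles$dm, allele),
                  logical(1))
    if (!any(idx)) rational(0) else sum(gd$probs[idx])
  }
  expect_true(marginal("WT") == rational(1, 2))
  expect_true(marginal("DM-full") == rational(1, 20))
  expect_true(marginal("DM-mO") == rational(9, 40))
  expect_true(marginal("DM-mC") == rational(9, 40))
})

test_that("a wild-type parent yields a single gamete class", {
  wt <- two_locus("female", c("WT", "WT"), c("WT", "WT"))
  gd <- gamete_distribution(wt, sim_params(), reg)
  expect_equal(length(gd), 1L)
  expect_true(gd$probs[1] == rational(1))
})

test_that("resolution boundary cases: p = 0 and p = 1", {
  mom <- two_locus("female", c("DM-full", "WT"), c("HELPER-mCe", "WT"))
  gd0 <- gamete_distribution(mom, sim_params(p = 0), reg)
  alleles0 <- unlist(lapply(gd0$outcomes, function(h) h$alleles$dm))
  expect_false(any(alleles0 %in% c("DM-mO", "DM-mC")))
  gd1 <- gamete_distribution(mom, sim_params(p = 1), reg)
  alleles1 <- unlist(lapply(gd1$outcomes, function(h) h$alleles$dm))
  expect_false(any(alleles1 == "DM-full"))
})

test_that("cre_active requires a Cre-carrying parent and p, b are bounded", {
  wt <- two_locus("female", c("DM-full", "WT"), c("WT", "WT"))
  expect_error(gamete_distribution(wt, sim_params(), reg, cre_active = TRUE),
               "Cre-carrying")
  expect_error(sim_params(p = 1.2), "\\[0, 1\\]")
  expect_error(sim_params(b = -0.1), "\\[0, 1\\]")
})

test_that("cross_exact reproduces the founder x helper cross", {
  mom <- two_locus("female", c("DM-full", "WT"), c("WT", "WT"))
  dad <- two_locus("male", c("WT", "WT"), c("HELPER-mCe", "HELPER-mCe"))
  cd <- class_distribution(cross_exact(mom, dad, sim_params(), reg), reg)
  expect_true(pmf_prob(cd, "mCe") == rational(1, 2))
  expect_true(pmf_prob(cd, "mCe+mO+mC") == rational(1, 2))
  expect_true(pmf_total(cd) == rational(1))
})

test_that("trans heterozygote x wild type gives 50/50 with no wild-type progeny", {
  mom <- two_locus("female", c("DM-mO", "DM-mC"), c("WT", "WT"))
  dad <- two_locus("male", c("WT", "WT"), c("WT", "WT"))
  cd <- class_distribution(cross_exact(mom, dad, sim_params(), reg), reg)
  expect_true(pmf_prob(cd, "mO") == rational(1, 2))
  expect_true(pmf_prob(cd, "mC") == rational(1, 2))
  expect_true(pmf_prob(cd, "") == rational(0))
})

test_that("heterozygote x heterozygote gives 1/4, 1/4, 1/2", {
  mom <- two_locus("female", c("DM-mO", "DM-mC"), c("WT", "WT"))
  dad <- two_locus("male", c("DM-mO", "DM-mC"), c("WT", "WT"))
  cd <- class_distribution(cross_exact(mom, dad, sim_params(), reg), reg)
  expect_true(pmf_prob(cd, "mO") == rational(1, 4))
  expect_true(pmf_prob(cd, "mC") == rational(1, 4))
  expect_true(pmf_prob(cd, "mO+mC") == rational(1, 2))
})

test_that("same-sex parents are rejected", {
  mom <- two_locus("female", c("WT", "WT"), c("WT", "WT"))
  expect_error(cross_exact(mom, mom, sim_params(), reg), "female mother")
})

test_that("phenotype is the dominant union of allele markers", {
  dbl <- two_locus("female", c("DM-full", "WT"), c("HELPER-mCe", "WT"))
  expect_equal(phenotype_of(dbl, reg), "mCe+mO+mC")
  wt <- two_locus("male", c("WT", "WT"), c("WT", "WT"))
  expect_equal(phenotype_of(wt, reg), "")
  homo <- two_locus("female", c("DM-mO", "DM-mO"), c("WT", "WT"))
  hemi <- two_locus("female", c("DM-mO", "WT"), c("WT", "WT"))
  expect_equal(phenotype_of(homo, reg), "mO")
  expect_equal(phenotype_of(hemi, reg), "mO")
  # cis full allele and trans heterozygote are phenotypically identical
  cis <- two_locus("female", c("DM-full", "WT"), c("WT", "WT"))
  trans <- two_locus("female", c("DM-mO", "DM-mC"), c("WT", "WT"))
  expect_equal(phenotype_of(cis, reg), phenotype_of(trans, reg))
})

test_that("class distribution of the post-recombination cross, exact and residual", {
  mom <- two_locus("female", c("DM-full", "WT"), c("HELPER-mCe", "WT"))
  dad <- two_locus("male", c("WT", "WT"), c("WT", "WT"))
  cd <- class_distribution(cross_exact(mom, dad, sim_params(p = 1), reg), reg)
  want <- setNames(
    list(c(1, 4), c(1, 4), c(1, 8), c(1, 8), c(1, 8), c(1, 8)),
    c("", "mCe", "mO", "mC", "mCe+mO", "mCe+mC"))
  for (k in seq_along(want)) {
    expect_true(pmf_prob(cd, names(want)[k]) ==
                  rational(want[[k]][1], want[[k]][2]))
  }
  cd9 <- class_distribution(cross_exact(mom, dad, sim_params(p = "9/10"), reg),
                            reg)
  expect_true(pmf_prob(cd9, "mO+mC") == rational(1, 40))
  expect_true(pmf_prob(cd9, "mCe+mO+mC") == rational(1, 40))
})

test_that("class distributions match the brute-force triple enumeration", {
  # registry variant in which the full allele carries its own Cre cassette,
  # so a single-locus parent can have an active germline
  reg_self <- reg
  reg_self$`DM-full`$cre <- TRUE
  alleles <- list(
    WT = list(markers = character(0)),
    `DM-full` = list(markers = c("mO", "mC"), resolvable = TRUE,
                     mO = "DM-mO", mC = "DM-mC"),
    `DM-mO` = list(markers = "mO"),
    `DM-mC` = list(markers = "mC"))
  cases <- list(
    list(m = c("DM-full", "WT"), f = c("WT", "WT"), p = 0.9, b = 0.5,
         cre_m = TRUE),
    list(m = c("DM-full", "WT"), f = c("DM-mC", "WT"), p = 0.7, b = 0.3,
         cre_m = TRUE),
    list(m = c("DM-mO", "DM-mC"), f = c("DM-mO", "DM-mC"), p = 1, b = 0.5,
         cre_m = FALSE))
  for (cs in cases) {
    mom <- genotype("female", dm = dm_locus(cs$m[1], cs$m[2]))
    dad <- genotype("male", dm = dm_locus(cs$f[1], cs$f[2]))
    got <- class_distribution(
      cross_exact(mom, dad, sim_params(p = cs$p, b = cs$b), reg_self,
                  cre_active_mother = cs$cre_m, cre_active_father = FALSE),
      reg_self)
    want <- oracle_single_locus_cross(cs$m, cs$f, alleles, cs$p, cs$b,
                                      cre_mother = cs$cre_m)
    expect_setequal(got$labels, names(want))
    for (lab in names(want)) {
      expect_equal(as.numeric(pmf_prob(got, lab)), pvec(want, lab),
                   tolerance = 1e-12)
    }
  }
})

test_that("sex ratio is exactly 1/2 : 1/2", {
  mom <- two_locus("female", c("DM-full", "WT"), c("HELPER-mCe", "WT"))
  dad <- two_locus("male", c("DM-mO", "WT"), c("WT", "WT"))
  d <- cross_exact(mom, dad, sim_params(), reg)
  females <- vapply(d$outcomes, function(g) g$sex == "female", logical(1))
  expect_true(sum(d$probs[females]) == rational(1, 2))
})

test_that("X-linked transmission: sons never inherit the paternal X transgene", {
  dad <- genotype("male", dm = locus("X", "DM-mO"))
  mom <- genotype("female", dm = locus("X", c("WT", "WT")))
  d <- cross_exact(mom, dad, sim_params(), reg)
  for (i in seq_along(d$keys)) {
    g <- d$outcomes[[i]]
    if (g$sex == "male") {
      expect_false("DM-mO" %in% g$loci$dm$alleles)
    } else {
      expect_true("DM-mO" %in% g$loci$dm$alleles)
    }
  }
})

test_that("viability filtering renormalizes to survivor-conditional ratios", {
  mom <- genotype("female", dm = dm_locus("DM-mO", "WT"))
  dad <- genotype("male", dm = dm_locus("DM-mO", "WT"))
  d <- cross_exact(mom, dad, sim_params(), reg)
  cd_all <- class_distribution(d, reg)
  expect_true(pmf_prob(cd_all, "mO") == rational(3, 4))
  no_homo <- sim_params(viable = function(g, r) zygosity(g, "dm") != "homozygous")
  cd_leth <- class_distribution(apply_viability(d, no_homo, reg), reg)
  expect_true(pmf_prob(cd_leth, "mO") == rational(2, 3))
  # no flags: identity
  expect_identical(apply_viability(d, sim_params(), reg), d)
  all_dead <- sim_params(viable = function(g, r) FALSE)
  expect_error(apply_viability(d, all_dead, reg), "no viable progeny")
})

test_that("zygosity distinguishes hemi-, hetero- and homozygous states", {
  expect_equal(zygosity(genotype("female", dm = dm_locus("DM-mO", "WT")), "dm"),
               "hemizygous")
  expect_equal(zygosity(genotype("female", dm = dm_locus("DM-mO", "DM-mC")), "dm"),
               "heterozygous")
  expect_equal(zygosity(genotype("female", dm = dm_locus("DM-mO", "DM-mO")), "dm"),
               "homozygous")
  expect_equal(zygosity(genotype("male", dm = locus("X", "DM-mO")), "dm"),
               "hemizygous")
  expect_equal(zygosity(genotype("female", dm = dm_locus("WT", "WT")), "dm"),
               "wild-type")
})

test_that("alleles_from_construct wires the engine products into the registry", {
  der <- alleles_from_construct(dual_marker_construct(), prefix = "DM2")
  expect_setequal(names(der), c("DM2-full", "DM2-mO", "DM2-mC"))
  expect_true(der$`DM2-full`$resolvable)
  expect_equal(der$`DM2-full`$resolved_mO, "DM2-mO")
  expect_error(alleles_from_construct(helper_marker_construct()),
               "does not resolve")
})
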