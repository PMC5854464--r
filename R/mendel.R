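#' Exact Mendelian cross enumeration
#'
#' Diploid genetics with unlinked loci on autosomes or the X chromosome,
#' female XX / male Xy sex determination (the y carries no loci), germline
#' Cre resolution of recombination-capable alleles, and phenotype inference
#' from dominant eye markers. Every distribution is exact: probabilities are
#' [rational()] numbers, and floats appear only at display or sampling time.
#'
#' @name mendel
NULL

# ---- alleles --------------------------------------------------------------

#' Define an allele
#'
#' An allele is a named construct state at one locus: wild type (no markers),
#' a full dual-marker allele that Cre can resolve, one of its single-marker
#' resolution products, or a helper allele expressing Cre.
#'
#' @param name allele label.
#' @param markers character subset of `c("mCe", "mO", "mC")` visible when
#'   the allele is present (dominant).
#' @param cre does the allele express Cre recombinase?
#' @param resolved_mO,resolved_mC names of the mO- and mC-retaining
#'   resolution products; supplying both marks the allele as Cre-resolvable.
#' @param construct optional `construct` backing the allele.
#' @return An `allele`.
#' @export
make_allele <- function(name, markers = character(0), cre = FALSE,
                        resolved_mO = NA_character_,
                        resolved_mC = NA_character_,
                        construct = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  markers <- as.character(markers)
  if (!all(markers %in% .MARKER_ORDER)) {
    stop("markers must be a subset of mCe, mO, mC", call. = FALSE)
  }
  resolvable <- !is.na(resolved_mO) && !is.na(resolved_mC)
  if (xor(is.na(resolved_mO), is.na(resolved_mC))) {
    stop("supply both resolution products or neither", call. = FALSE)
  }
  structure(list(name = name, markers = markers, cre = isTRUE(cre),
                 resolvable = resolvable, resolved_mO = resolved_mO,
                 resolved_mC = resolved_mC, construct = construct),
            class = "allele")
}

#' Standard allele registry for the dual-marker design
#'
#' Wild type, the full (pre-recombination) dual-marker allele with its two
#' single-marker resolution products, and the Cre helper allele marked with
#' mCerulean.
#'
#' @return named list of [make_allele()] objects.
#' @export
standard_alleles <- function() {
  reg <- list(
    make_allele("WT"),
    make_allele("DM-full", markers = c("mO", "mC"),
                resolved_mO = "DM-mO", resolved_mC = "DM-mC"),
    make_allele("DM-mO", markers = "mO"),
    make_allele("DM-mC", markers = "mC"),
    make_allele("HELPER-mCe", markers = "mCe", cre = TRUE)
  )
  stats::setNames(reg, vapply(reg, `[[`, character(1), "name"))
}

#' Derive alleles from a construct via the recombination engine
#'
#' Runs [stable_products()] on the construct; requires that every stable
#' product retains exactly one marker (the defining property of the
#' interweaved design) and creates three alleles: the full resolvable allele
#' plus its mO- and mC-retaining products.
#'
#' @param x a `construct` carrying markers mO and mC.
#' @param prefix name prefix for the derived alleles (defaults to the
#'   construct name).
#' @return named list of three alleles (`<prefix>-full`, `<prefix>-mO`,
#'   `<prefix>-mC`).
#' @export
alleles_from_construct <- function(x, prefix = x$name) {
  md <- marker_distribution(stable_products(x))
  if (!setequal(md$labels, c("mO", "mC"))) {
    stop(sprintf(
      "construct '%s' does not resolve into one mO- and one mC-retaining product (got: %s)",
      x$name, paste(md$labels, collapse = ", ")), call. = FALSE)
  }
  full <- make_allele(paste0(prefix, "-full"),
                      markers = sort(unique(construct_markers(x))),
                      resolved_mO = paste0(prefix, "-mO"),
                      resolved_mC = paste0(prefix, "-mC"),
                      construct = x)
  reg <- list(full,
              make_allele(paste0(prefix, "-mO"), markers = "mO"),
              make_allele(paste0(prefix, "-mC"), markers = "mC"))
  stats::setNames(reg, vapply(reg, `[[`, character(1), "name"))
}

.get_allele <- function(registry, name) {
  a <- registry[[name]]
  if (is.null(a)) stop(sprintf("unknown allele '%s'", name), call. = FALSE)
  a
}

# ---- genotypes ------------------------------------------------------------

#' Define a locus assignment within a genotype
#'
#' @param chromosome `"X"` or an autosome label (e.g. `"autosome-1"`); loci
#'   are pairwise unlinked regardless of label.
#' @param alleles character vector of allele names: two for an autosomal
#'   locus or a female X locus, one for a male X locus.
#' @return A locus assignment list.
#' @export
locus <- function(chromosome, alleles) {
  stopifnot(is.character(chromosome), length(chromosome) == 1L)
  list(chromosome = chromosome, alleles = as.character(alleles))
}

#' Define a diploid genotype
#'
#' @param sex `"female"` (XX) or `"male"` (Xy; the y carries no loci).
#' @param ... named [locus()] assignments.
#' @param loci alternatively, a named list of [locus()] assignments.
#' @return A `genotype`.
#' @examples
#' genotype("female",
#'          dm = locus("autosome-1", c("DM-full", "WT")),
#'          helper = locus("autosome-2", c("WT", "WT")))
#' @export
genotype <- function(sex = c("female", "male"), ..., loci = NULL) {
  sex <- match.arg(sex)
  if (is.null(loci)) loci <- list(...)
  if (length(loci) == 0L || is.null(names(loci)) || any(names(loci) == "")) {
    stop("loci must be a named list", call. = FALSE)
  }
  for (nm in names(loci)) {
    l <- loci[[nm]]
    expected <- if (l$chromosome == "X" && sex == "male") 1L else 2L
    if (length(l$alleles) != expected) {
      stop(sprintf(
        "locus '%s' (%s) requires %d allele(s) for a %s, got %d",
        nm, l$chromosome, expected, sex, length(l$alleles)), call. = FALSE)
    }
  }
  structure(list(sex = sex, loci = loci[order(names(loci))]),
            class = "genotype")
}

#' Canonical genotype key (allele pairs unordered within a locus)
#' @param g a `genotype`.
#' @return character scalar.
#' @export
genotype_key <- function(g) {
  loci <- vapply(names(g$loci), function(nm) {
    l <- g$loci[[nm]]
    paste0(nm, "=", paste(sort(l$alleles), collapse = "/"))
  }, character(1))
  paste0(g$sex, ";", paste(loci, collapse = ";"))
}

#' @export
format.genotype <- function(x, ...) paste0("<genotype ", genotype_key(x), ">")

#' @export
print.genotype <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Does a genotype carry a Cre-expressing allele?
#' @param g a `genotype`.
#' @param registry allele registry.
#' @return `TRUE`/`FALSE`.
#' @export
carries_cre <- function(g, registry = standard_alleles()) {
  any(vapply(unlist(lapply(g$loci, `[[`, "alleles")),
             function(a) .get_allele(registry, a)$cre, logical(1)))
}

#' Zygosity of a genotype at one locus
#'
#' `"wild-type"`, `"hemizygous"` (one non-WT allele against wild type, or a
#' single-copy male X allele), `"heterozygous"` (two distinct non-WT alleles
#' in trans) or `"homozygous"` (two copies of one non-WT allele).
#'
#' @param g a `genotype`.
#' @param locus_name which locus.
#' @param wt name of the wild-type allele.
#' @return character scalar.
#' @export
zygosity <- function(g, locus_name, wt = "WT") {
  l <- g$loci[[locus_name]]
  if (is.null(l)) stop(sprintf("no locus '%s'", locus_name), call. = FALSE)
  a <- l$alleles
  nonwt <- a[a != wt]
  if (length(nonwt) == 0L) return("wild-type")
  if (length(a) == 1L) return("hemizygous")       # male X
  if (length(nonwt) == 1L) return("hemizygous")
  if (nonwt[1] == nonwt[2]) return("homozygous")
  "heterozygous"
}

# ---- simulation parameters -----------------------------------------------

#' Germline recombination parameters and viability/fertility flags
#'
#' @param p germline recombination efficiency: the probability that a
#'   transmitted Cre-resolvable allele is resolved into a single-marker
#'   allele (default 1, complete recombination).
#' @param b excision bias: probability that a resolved allele retains mO
#'   (default 1/2, the unbiased split of the uniform-event-choice model).
#' @param viable optional predicate `function(genotype, registry)`
#'   returning `FALSE` for genotypes that die before scoring; `NULL` means
#'   all viable.
#' @param fertile optional predicate `function(genotype, registry)`
#'   returning `FALSE` for sterile genotypes; `NULL` means all fertile.
#' @return A `sim_params` object.
#' @export
sim_params <- function(p = 1, b = 1 / 2, viable = NULL, fertile = NULL) {
  p <- as_rational(p)
  b <- as_rational(b)
  if (length(p) != 1L || !.rat_in_unit(p)) {
    stop("p must be a single value in [0, 1]", call. = FALSE)
  }
  if (length(b) != 1L || !.rat_in_unit(b)) {
    stop("b must be a single value in [0, 1]", call. = FALSE)
  }
  if (!is.null(viable)) stopifnot(is.function(viable))
  if (!is.null(fertile)) stopifnot(is.function(fertile))
  structure(list(p = p, b = b, viable = viable, fertile = fertile),
            class = "sim_params")
}

# ---- genotype/haplotype distributions -------------------------------------

#' Genotype distributions (internal container over arbitrary outcomes)
#' @keywords internal
.gdist <- function(outcomes, probs, keys) {
  structure(list(outcomes = outcomes, probs = probs, keys = keys),
            class = "gdist")
}

.gdist_merge <- function(outcomes, probs, keys) {
  u <- unique(keys)
  idx <- match(u, keys)
  out_probs <- rational(rep(0, length(u)))
  for (i in seq_along(keys)) {
    k <- match(keys[i], u)
    out_probs[k] <- out_probs[k] + probs[i]
  }
  .gdist(outcomes[idx], out_probs, u)
}

#' @export
length.gdist <- function(x) length(x$keys)

#' @export
format.gdist <- function(x, ...) {
  paste0("<distribution over ", length(x$keys), " outcome(s)>")
}

#' @export
print.gdist <- function(x, ...) {
  cat(format(x), "\n")
  for (i in seq_along(x$keys)) {
    cat(sprintf("  %-60s %s\n", x$keys[i], format(x$probs[i])))
  }
  invisible(x)
}

#' Condition a genotype distribution on a predicate
#'
#' Keeps the outcomes for which `predicate` is `TRUE` and renormalizes
#' exactly.
#'
#' @param d a genotype distribution (from [cross_exact()]).
#' @param predicate `function(outcome)` returning `TRUE`/`FALSE`.
#' @return conditioned distribution.
#' @export
condition_gdist <- function(d, predicate) {
  keep <- vapply(d$outcomes, predicate, logical(1))
  if (!any(keep)) stop("conditioning on zero-probability event", call. = FALSE)
  total <- sum(d$probs[keep])
  if (as.numeric(total) == 0) {
    stop("conditioning on zero-probability event", call. = FALSE)
  }
  .gdist(d$outcomes[keep], d$probs[keep] / total, d$keys[keep])
}

# ---- gametes --------------------------------------------------------------

.hap_key <- function(h) {
  loci <- vapply(names(h$alleles), function(nm) {
    paste0(nm, "=", h$alleles[[nm]])
  }, character(1))
  paste0(h$sex_chrom, ";", paste(loci, collapse = ";"))
}

#' Exact gamete distribution of one parent
#'
#' Each locus segregates 1/2 : 1/2 independently. Males produce X- and
#' y-bearing gametes with probability 1/2 each; X-linked alleles are carried
#' only by X-bearing gametes. When the parent's germline expresses Cre
#' (`cre_active`), every transmitted Cre-resolvable allele is independently
#' replaced with probability `p` by a resolved allele -- mO-retaining with
#' probability `b`, mC-retaining with probability `1 - b`.
#'
#' @param parent a [genotype()].
#' @param params [sim_params()].
#' @param registry allele registry.
#' @param cre_active `NULL` (default) activates germline resolution iff the
#'   parent carries a Cre allele; `TRUE`/`FALSE` forces it.
#' @return A distribution over haplotypes: each outcome has `sex_chrom`
#'   (`"X"` or `"y"`) and a named list `alleles` (locus -> transmitted allele
#'   name; X-linked loci are absent from y-bearing gametes).
#' @export
gamete_distribution <- function(parent, params = sim_params(),
                                registry = standard_alleles(),
                                cre_active = NULL) {
  stopifnot(inherits(parent, "genotype"), inherits(params, "sim_params"))
  if (is.null(cre_active)) cre_active <- carries_cre(parent, registry)
  if (cre_active && !carries_cre(parent, registry)) {
    stop("cre_active = TRUE requires a Cre-carrying parent", call. = FALSE)
  }

  haps <- list(list(sex_chrom = "X", alleles = list()))
  probs <- rational(1)
  if (parent$sex == "male") {
    haps <- list(list(sex_chrom = "X", alleles = list()),
                 list(sex_chrom = "y", alleles = list()))
    probs <- rational(c(1, 1), 2)
  }

  branch <- function(haps, probs, f) {
    out_h <- list(); out_p <- list()
    for (i in seq_along(haps)) {
      res <- f(haps[[i]])   # list of list(hap, w) with w rational
      for (r in res) {
        out_h[[length(out_h) + 1L]] <- r$hap
        out_p[[length(out_p) + 1L]] <- probs[i] * r$w
      }
    }
    list(haps = out_h, probs = do.call(c.rational, out_p))
  }

  for (nm in names(parent$loci)) {
    l <- parent$loci[[nm]]
    st <- branch(haps, probs, function(h) {
      if (l$chromosome == "X") {
        if (parent$sex == "male") {
          if (h$sex_chrom == "y") return(list(list(hap = h, w = rational(1))))
          h$alleles[[nm]] <- l$alleles[[1L]]
          return(list(list(hap = h, w = rational(1))))
        }
      }
      lapply(l$alleles, function(a) {
        h2 <- h
        h2$alleles[[nm]] <- a
        list(hap = h2, w = rational(1, 2))
      })
    })
    haps <- st$haps; probs <- st$probs
  }

  if (cre_active) {
    p <- params$p; b <- params$b
    for (nm in names(parent$loci)) {
      st <- branch(haps, probs, function(h) {
        a_name <- h$alleles[[nm]]
        if (is.null(a_name)) return(list(list(hap = h, w = rational(1))))
        a <- .get_allele(registry, a_name)
        if (!a$resolvable) return(list(list(hap = h, w = rational(1))))
        out <- list()
        if (p != rational(1)) {
          out[[length(out) + 1L]] <- list(hap = h, w = rational(1) - p)
        }
        if (p != rational(0)) {
          if (b != rational(0)) {
            h_o <- h; h_o$alleles[[nm]] <- a$resolved_mO
            out[[length(out) + 1L]] <- list(hap = h_o, w = p * b)
          }
          if (b != rational(1)) {
            h_c <- h; h_c$alleles[[nm]] <- a$resolved_mC
            out[[length(out) + 1L]] <- list(hap = h_c, w = p * (rational(1) - b))
          }
        }
        out
      })
      haps <- st$haps; probs <- st$probs
    }
  }

  keys <- vapply(haps, .hap_key, character(1))
  .gdist_merge(haps, probs, keys)
}

# ---- crosses --------------------------------------------------------------

#' Exact offspring distribution of a cross
#'
#' Product of the parental gamete distributions; the paternal gamete's sex
#' chromosome assigns offspring sex (X-bearing -> daughter, y-bearing ->
#' son). Probabilities are exact rationals summing to 1.
#'
#' @param mother,father [genotype()]s (female and male respectively, sharing
#'   the same locus set).
#' @param params [sim_params()].
#' @param registry allele registry.
#' @param cre_active_mother,cre_active_father override automatic germline
#'   Cre activation per parent (see [gamete_distribution()]).
#' @return A distribution (`gdist`) over offspring [genotype()]s.
#' @export
cross_exact <- function(mother, father, params = sim_params(),
                        registry = standard_alleles(),
                        cre_active_mother = NULL, cre_active_father = NULL) {
  stopifnot(inherits(mother, "genotype"), inherits(father, "genotype"))
  if (mother$sex != "female" || father$sex != "male") {
    stop("cross requires a female mother and a male father", call. = FALSE)
  }
  if (!identical(names(mother$loci), names(father$loci))) {
    stop("parents must be defined over the same loci", call. = FALSE)
  }
  gm <- gamete_distribution(mother, params, registry, cre_active_mother)
  gf <- gamete_distribution(father, params, registry, cre_active_father)

  outcomes <- list(); probs <- list(); keys <- character(0)
  for (i in seq_along(gm$keys)) {
    for (j in seq_along(gf$keys)) {
      hm <- gm$outcomes[[i]]; hf <- gf$outcomes[[j]]
      sex <- if (hf$sex_chrom == "X") "female" else "male"
      loci <- list()
      for (nm in names(mother$loci)) {
        chrom <- mother$loci[[nm]]$chromosome
        if (chrom == "X" && sex == "male") {
          loci[[nm]] <- locus(chrom, hm$alleles[[nm]])
        } else {
          loci[[nm]] <- locus(chrom, c(hm$alleles[[nm]], hf$alleles[[nm]]))
        }
      }
      child <- genotype(sex, loci = loci)
      outcomes[[length(outcomes) + 1L]] <- child
      probs[[length(probs) + 1L]] <- gm$probs[i] * gf$probs[j]
      keys <- c(keys, genotype_key(child))
    }
  }
  .gdist_merge(outcomes, do.call(c.rational, probs), keys)
}

# ---- phenotypes -----------------------------------------------------------

#' All eight phenotype classes, in canonical column order
#'
#' The subsets of \{mCe, mO, mC\}: `""` (wild-type appearance), `"mCe"`,
#' `"mO"`, `"mC"`, `"mCe+mO"`, `"mCe+mC"`, `"mO+mC"`, `"mCe+mO+mC"`.
#' @return character vector of length 8.
#' @export
phenotype_classes <- function() {
  c("", "mCe", "mO", "mC", "mCe+mO", "mCe+mC", "mO+mC", "mCe+mO+mC")
}

#' Phenotype class of a genotype
#'
#' Union of the marker sets over all alleles (one copy suffices: dominance).
#' Not injective -- a cis dual-marker allele and a trans heterozygote both
#' display `"mO+mC"`.
#'
#' @param g a [genotype()].
#' @param registry allele registry.
#' @return class label (see [phenotype_classes()]).
#' @export
phenotype_of <- function(g, registry = standard_alleles()) {
  markers <- unlist(lapply(unlist(lapply(g$loci, `[[`, "alleles")),
                           function(a) .get_allele(registry, a)$markers))
  .marker_class(markers)
}

#' Pushforward of an offspring distribution to phenotype classes
#'
#' @param d offspring distribution from [cross_exact()].
#' @param registry allele registry.
#' @param by_sex split classes by offspring sex?
#' @return A [pmf()] over class labels (or `sex|class` labels when
#'   `by_sex = TRUE`), summing exactly to 1.
#' @export
class_distribution <- function(d, registry = standard_alleles(),
                               by_sex = FALSE) {
  labels <- vapply(seq_along(d$keys), function(i) {
    cl <- phenotype_of(d$outcomes[[i]], registry)
    if (by_sex) paste(d$outcomes[[i]]$sex, cl, sep = "|") else cl
  }, character(1))
  out <- .pmf_accumulate(labels, d$probs)
  if (!by_sex) {
    ord <- order(match(out$labels, phenotype_classes()))
    out <- pmf(out$labels[ord], out$probs[ord])
  }
  out
}

#' Remove lethal genotypes and renormalize
#'
#' Zeroes the probability of genotypes flagged non-viable by
#' `params$viable` and renormalizes exactly, yielding survivor-conditional
#' ratios. Identity when no viability predicate is set.
#'
#' @param d offspring distribution from [cross_exact()].
#' @param params [sim_params()] with a `viable` predicate.
#' @param registry allele registry.
#' @return filtered distribution.
#' @export
apply_viability <- function(d, params, registry = standard_alleles()) {
  if (is.null(params$viable)) return(d)
  keep <- vapply(d$outcomes, function(g) isTRUE(params$viable(g, registry)),
                 logical(1))
  if (!any(keep)) stop("no viable progeny", call. = FALSE)
  total <- sum(d$probs[keep])
  .gdist(d$outcomes[keep], d$probs[keep] / total, d$keys[keep])
}
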