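#' Lox recombination sites and transgene constructs
#'
#' A Lox site is the 34-bp Cre recombinase recognition sequence: two 13-bp
#' arms flanking an asymmetric 8-bp spacer. Spacer identity decides whether
#' Cre can recombine two sites; the arms are essentially invariant between
#' engineered Lox variants. A construct is modeled as an ordered (5'->3')
#' list of genetic elements on one chromosome copy -- Lox sites, marker
#' cassettes, and inert segments. Inter-element sequence is deliberately not
#' modeled: recombination outcomes depend on element topology and Lox
#' spacers only.
#'
#' @name constructs
NULL

#' Canonical LoxP and LoxN sequences (34 nt)
#'
#' The two spacer-variant Lox sites used by the dual-marker interweaved-Lox
#' design. Their spacers differ at two positions, which makes the two site
#' types incompatible with each other while each remains self-compatible.
#' @format Character scalars of 34 characters.
#' @export
LOXP_SEQ <- "ATAACTTCGTATAGCATACATTATACGAAGTTAT"

#' @rdname LOXP_SEQ
#' @export
LOXN_SEQ <- "ATAACTTCGTATAGTATACCTTATACGAAGTTAT"

.revcomp <- function(s) {
  vapply(s, function(x) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", x), "", fixed = TRUE)[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Parse a 34-nt Lox site
#'
#' Splits a 34-nt DNA string into its 13-nt arms (positions 1-13 and 22-34)
#' and 8-nt spacer (positions 14-21).
#'
#' @param seq 34-character DNA string over A, C, G, T.
#' @param orientation `"forward"` or `"reverse"`. The sequence is stored as
#'   given; a reverse-orientation site contributes the reverse complement of
#'   its stored spacer when compatibility is decided.
#' @return A `lox_site` object with fields `arm5`, `spacer`, `arm3`,
#'   `orientation`.
#' @examples
#' parse_lox_site(LOXP_SEQ)$spacer  # "GCATACAT"
#' @export
parse_lox_site <- function(seq, orientation = c("forward", "reverse")) {
  orientation <- match.arg(orientation)
  if (!is.character(seq) || length(seq) != 1L) {
    stop("seq must be a single character string", call. = FALSE)
  }
  if (nchar(seq) != 34L) {
    stop(sprintf("lox site must be 34 nt, got %d", nchar(seq)), call. = FALSE)
  }
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% c("A", "C", "G", "T"))
  if (length(bad) > 0L) {
    stop(sprintf("invalid base '%s' at position %d", chars[bad[1]], bad[1]),
         call. = FALSE)
  }
  structure(list(arm5 = substr(seq, 1L, 13L),
                 spacer = substr(seq, 14L, 21L),
                 arm3 = substr(seq, 22L, 34L),
                 orientation = orientation),
            class = "lox_site")
}

#' @export
format.lox_site <- function(x, ...) {
  sprintf("<lox_site %s %s|%s|%s>", x$orientation, x$arm5, x$spacer, x$arm3)
}

#' @export
print.lox_site <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Serialize a lox site back to its 34-nt string
#' @param site a `lox_site`.
#' @return The stored 34-character sequence.
#' @export
lox_sequence <- function(site) {
  paste0(site$arm5, site$spacer, site$arm3)
}

#' Effective spacer of a site, in the forward reading frame
#'
#' For a forward site this is the stored spacer; for a reverse site it is the
#' reverse complement of the stored spacer, so that two sites are compared in
#' a common frame.
#' @param site a `lox_site`.
#' @return 8-character string.
#' @export
effective_spacer <- function(site) {
  if (site$orientation == "reverse") .revcomp(site$spacer) else site$spacer
}

#' Can Cre recombine two Lox sites?
#'
#' Two sites are compatible iff their effective spacers are identical.
#' Arm differences do not affect compatibility (engineered Lox variants vary
#' only in the spacer); [validate_construct()] reports arm mismatches between
#' otherwise compatible sites as warnings.
#'
#' @param a,b `lox_site` objects.
#' @return `TRUE` or `FALSE`.
#' @examples
#' lox_compatible(parse_lox_site(LOXP_SEQ), parse_lox_site(LOXN_SEQ))  # FALSE
#' @export
lox_compatible <- function(a, b) {
  stopifnot(inherits(a, "lox_site"), inherits(b, "lox_site"))
  identical(effective_spacer(a), effective_spacer(b))
}

#' Create a genetic element
#'
#' @param kind one of `"lox"`, `"marker"`, `"cassette"`, `"backbone"`,
#'   `"other"`.
#' @param id element label, unique within a construct.
#' @param site a `lox_site` (required iff `kind == "lox"`).
#' @param marker marker name (`"mO"`, `"mC"`, `"mCe"`) when
#'   `kind == "marker"`.
#' @param orientation element orientation, flipped when the element lies
#'   inside an inverted segment.
#' @return A `genetic_element`.
#' @export
genetic_element <- function(kind, id, site = NULL, marker = NULL,
                            orientation = c("forward", "reverse")) {
  kind <- match.arg(kind, c("lox", "marker", "cassette", "backbone", "other"))
  orientation <- match.arg(orientation)
  if (kind == "lox" && !inherits(site, "lox_site")) {
    stop("lox element requires a lox_site payload", call. = FALSE)
  }
  if (kind != "lox" && !is.null(site)) {
    stop("only lox elements carry a lox_site payload", call. = FALSE)
  }
  if (kind == "lox") orientation <- site$orientation
  structure(list(kind = kind, id = as.character(id), site = site,
                 marker = marker, orientation = orientation),
            class = "genetic_element")
}

#' Create a construct from ordered elements
#'
#' @param name construct label.
#' @param elements list of [genetic_element()]s, ordered 5' to 3'.
#' @return A `construct`.
#' @export
construct <- function(name, elements) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!all(vapply(elements, inherits, logical(1), "genetic_element"))) {
    stop("elements must all be genetic_element objects", call. = FALSE)
  }
  structure(list(name = name, elements = elements), class = "construct")
}

#' @export
format.construct <- function(x, ...) {
  ids <- vapply(x$elements, function(e) {
    if (e$orientation == "reverse") paste0("<", e$id) else e$id
  }, character(1))
  sprintf("<construct %s: %s>", x$name, paste(ids, collapse = "-"))
}

#' @export
print.construct <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Marker names carried by a construct
#' @param x a `construct`.
#' @return character vector of marker names (possibly empty).
#' @export
construct_markers <- function(x) {
  m <- unlist(lapply(x$elements, function(e) {
    if (e$kind == "marker") e$marker else NULL
  }))
  if (is.null(m)) character(0) else m
}

# canonical marker display order (helper marker first, then the two
# construct markers), matching the progeny-class column layout
.MARKER_ORDER <- c("mCe", "mO", "mC")

# canonical class label for a marker set: ""(wild type), "mO", "mCe+mO+mC", ...
.marker_class <- function(markers) {
  paste(intersect(.MARKER_ORDER, unique(markers)), collapse = "+")
}

.lox_elements <- function(x) {
  Filter(function(e) e$kind == "lox", x$elements)
}

#' All compatible Lox site pairs of a construct
#'
#' @param x a `construct`.
#' @return data frame with columns `site_a`, `site_b` (element ids, in 5'->3'
#'   order) and `event_type` (`"excision"` for same-orientation pairs,
#'   `"inversion"` for opposite-orientation pairs). Zero rows when no pair is
#'   compatible.
#' @export
compatible_pairs <- function(x) {
  stopifnot(inherits(x, "construct"))
  lox <- .lox_elements(x)
  out <- list()
  if (length(lox) >= 2L) {
    for (i in seq_len(length(lox) - 1L)) {
      for (j in seq(i + 1L, length(lox))) {
        a <- lox[[i]]; b <- lox[[j]]
        if (lox_compatible(a$site, b$site)) {
          out[[length(out) + 1L]] <- data.frame(
            site_a = a$id, site_b = b$id,
            event_type = if (a$orientation == b$orientation) "excision"
                         else "inversion",
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(site_a = character(0), site_b = character(0),
                      event_type = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Validate a construct
#'
#' Reports malformed Lox payloads, duplicate element ids, arm mismatches
#' between compatible sites (warning only: compatibility is decided by the
#' spacer alone) and, as an informational finding, the number of compatible
#' site pairs.
#'
#' @param x a `construct`.
#' @return data frame of findings with columns `level` (`"error"`,
#'   `"warning"`, `"info"`), `id` and `message`. The compatible-pair count is
#'   also attached as attribute `n_compatible_pairs`.
#' @export
validate_construct <- function(x) {
  stopifnot(inherits(x, "construct"))
  findings <- list()
  add <- function(level, id, message) {
    findings[[length(findings) + 1L]] <<- data.frame(
      level = level, id = id, message = message, stringsAsFactors = FALSE)
  }
  ids <- vapply(x$elements, `[[`, character(1), "id")
  dup <- unique(ids[duplicated(ids)])
  for (d in dup) add("error", d, "duplicate element id")
  for (e in x$elements) {
    if (e$kind == "lox") {
      seq <- lox_sequence(e$site)
      if (nchar(seq) != 34L || grepl("[^ACGT]", seq)) {
        add("error", e$id, "malformed lox site payload")
      }
    }
    if (e$kind == "lox" && is.null(e$site)) {
      add("error", e$id, "lox element without site payload")
    }
  }
  pairs <- compatible_pairs(x)
  if (nrow(pairs) > 0L) {
    lox <- .lox_elements(x)
    names(lox) <- vapply(lox, `[[`, character(1), "id")
    for (k in seq_len(nrow(pairs))) {
      a <- lox[[pairs$site_a[k]]]; b <- lox[[pairs$site_b[k]]]
      if (!identical(a$site$arm5, b$site$arm5) ||
          !identical(a$site$arm3, b$site$arm3)) {
        add("warning", pairs$site_a[k],
            sprintf("arm mismatch with compatible site %s", pairs$site_b[k]))
      }
    }
  }
  add("info", NA_character_,
      sprintf("%d compatible site pair(s)", nrow(pairs)))
  out <- do.call(rbind, findings)
  attr(out, "n_compatible_pairs") <- nrow(pairs)
  out
}

# ---- bundled construct builders ------------------------------------------

#' Canonical dual-marker interweaved-Lox construct
#'
#' The element order is LoxP--mO--LoxN--LoxP--mC--LoxN: each marker is
#' flanked upstream by a LoxP and downstream by a LoxN site, so the two Lox
#' pairs interweave. Any single Cre excision removes one marker together with
#' one site of each type and leaves the remaining marker flanked by an
#' incompatible LoxP/LoxN pair, which freezes the outcome.
#'
#' @param name construct label.
#' @return A `construct`.
#' @export
dual_marker_construct <- function(name = "dualmark") {
  construct(name, list(
    genetic_element("lox", "loxP.1", site = parse_lox_site(LOXP_SEQ)),
    genetic_element("marker", "mO.cassette", marker = "mO"),
    genetic_element("lox", "loxN.1", site = parse_lox_site(LOXN_SEQ)),
    genetic_element("lox", "loxP.2", site = parse_lox_site(LOXP_SEQ)),
    genetic_element("marker", "mC.cassette", marker = "mC"),
    genetic_element("lox", "loxN.2", site = parse_lox_site(LOXN_SEQ))
  ))
}

#' Tandem-duplicated (nested-insertion) dual-marker construct
#'
#' Emulates a nested insertion: the transgene inserted into the backbone of a
#' second copy of the transformation vector, so the integrated unit carries
#' two stitched copies of the dual-marker cassette in tandem. Cre excises
#' nearly one full "stitched equivalent", and every stable product retains
#' exactly one marker.
#'
#' @param name construct label.
#' @return A `construct`.
#' @export
nested_dual_marker_construct <- function(name = "dualmark.nested") {
  copy <- function(tag) list(
    genetic_element("lox", paste0("loxP.1", tag), site = parse_lox_site(LOXP_SEQ)),
    genetic_element("marker", paste0("mO.cassette", tag), marker = "mO"),
    genetic_element("lox", paste0("loxN.1", tag), site = parse_lox_site(LOXN_SEQ)),
    genetic_element("lox", paste0("loxP.2", tag), site = parse_lox_site(LOXP_SEQ)),
    genetic_element("marker", paste0("mC.cassette", tag), marker = "mC"),
    genetic_element("lox", paste0("loxN.2", tag), site = parse_lox_site(LOXN_SEQ))
  )
  construct(name, c(copy(".a"),
                    list(genetic_element("backbone", "vector.backbone")),
                    copy(".b")))
}

#' Cre-helper marker cassette construct (no Lox sites)
#'
#' The helper transgene: a Cre recombinase expression cassette plus an
#' mCerulean eye marker, with no Lox sites of its own, so it is inert under
#' Cre.
#'
#' @param name construct label.
#' @return A `construct`.
#' @export
helper_marker_construct <- function(name = "cre.helper") {
  construct(name, list(
    genetic_element("cassette", "cre.cassette"),
    genetic_element("marker", "mCe.cassette", marker = "mCe")
  ))
}

# ---- config serialization -------------------------------------------------

.element_to_list <- function(e) {
  out <- list(kind = e$kind, id = e$id, orientation = e$orientation)
  if (e$kind == "lox") out$sequence <- lox_sequence(e$site)
  if (e$kind == "marker") out$marker <- e$marker
  out
}

.element_from_list <- function(l) {
  kind <- l$kind
  site <- NULL
  if (identical(kind, "lox")) {
    site <- parse_lox_site(l$sequence,
                           orientation = l$orientation %||% "forward")
  }
  genetic_element(kind, l$id, site = site, marker = l$marker,
                  orientation = l$orientation %||% "forward")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read / write construct configuration files
#'
#' Constructs are stored in a YAML document with a top-level `constructs`
#' list; each entry has a `name` and ordered `elements` (kind, id,
#' orientation, 34-nt `sequence` for lox elements, `marker` name for marker
#' elements). Serialization round-trips losslessly.
#'
#' @param path file path.
#' @return `read_construct_config()` returns a named list of `construct`
#'   objects.
#' @export
read_construct_config <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$constructs)) {
    stop("construct config must have a top-level 'constructs' list",
         call. = FALSE)
  }
  out <- lapply(doc$constructs, function(cd) {
    construct(cd$name, lapply(cd$elements, .element_from_list))
  })
  names(out) <- vapply(out, `[[`, character(1), "name")
  out
}

#' @rdname read_construct_config
#' @param constructs named list of `construct` objects.
#' @export
write_construct_config <- function(constructs, path) {
  doc <- list(constructs = lapply(constructs, function(x) {
    list(name = x$name, elements = lapply(x$elements, .element_to_list))
  }))
  names(doc$constructs) <- NULL
  yaml::write_yaml(doc, path)
  invisible(path)
}
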