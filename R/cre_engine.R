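#' Cre recombination event enumeration and stable products
#'
#' Cre recombination between two compatible Lox sites in the same orientation
#' excises the intervening segment (the excised circle is lost from the
#' genome); opposite orientations invert it. Starting from a construct, the
#' engine explores the full event graph and returns the exact probability of
#' every stable (terminal) product under the uniform-event-choice model: at
#' each non-terminal state every available event is equally likely. The
#' interweaved dual-marker design makes this split exactly 1/2 : 1/2; real
#' Cre kinetics are not modeled, and a downstream excision-bias parameter can
#' override the split.
#'
#' @name cre_engine
NULL

#' Enumerate recombination events available on a construct
#'
#' One event per unordered compatible site pair.
#'
#' @param x a `construct`.
#' @return data frame with columns `site_a`, `site_b`, `event_type`.
#' @export
enumerate_events <- function(x) {
  compatible_pairs(x)
}

.element_index <- function(x, id) {
  ids <- vapply(x$elements, `[[`, character(1), "id")
  match(id, ids)
}

#' Apply one recombination event to a construct
#'
#' Excision removes every element strictly between the two sites plus one of
#' the two sites, leaving a single hybrid site (5' arm and orientation of the
#' upstream site, 3' arm of the downstream site, shared spacer). Inversion
#' reverses element order and flips orientations strictly between the sites.
#'
#' @param x a `construct`.
#' @param event one row of [enumerate_events()] (data frame or list with
#'   `site_a`, `site_b`, `event_type`).
#' @return The product `construct`.
#' @export
apply_event <- function(x, event) {
  stopifnot(inherits(x, "construct"))
  if (is.data.frame(event)) {
    stopifnot(nrow(event) == 1L)
    event <- as.list(event)
  }
  i <- .element_index(x, event$site_a)
  j <- .element_index(x, event$site_b)
  if (is.na(i) || is.na(j)) stop("event sites not found in construct", call. = FALSE)
  if (i > j) { tmp <- i; i <- j; j <- tmp }
  a <- x$elements[[i]]; b <- x$elements[[j]]
  if (a$kind != "lox" || b$kind != "lox" || !lox_compatible(a$site, b$site)) {
    stop("event is not applicable to this construct", call. = FALSE)
  }
  same <- a$orientation == b$orientation
  expected <- if (same) "excision" else "inversion"
  if (!identical(event$event_type, expected)) {
    stop(sprintf("event type '%s' inconsistent with site orientations (%s)",
                 event$event_type, expected), call. = FALSE)
  }
  if (expected == "excision") {
    hybrid_site <- structure(list(arm5 = a$site$arm5,
                                  spacer = a$site$spacer,
                                  arm3 = b$site$arm3,
                                  orientation = a$orientation),
                             class = "lox_site")
    hybrid <- genetic_element("lox", paste0(a$id, "~", b$id),
                              site = hybrid_site)
    keep_left <- if (i > 1L) x$elements[seq_len(i - 1L)] else list()
    keep_right <- if (j < length(x$elements)) {
      x$elements[seq(j + 1L, length(x$elements))]
    } else list()
    construct(x$name, c(keep_left, list(hybrid), keep_right))
  } else {
    elements <- x$elements
    if (j - i > 1L) {
      inner <- elements[seq(i + 1L, j - 1L)]
      inner <- rev(lapply(inner, function(e) {
        e$orientation <- if (e$orientation == "forward") "reverse" else "forward"
        if (e$kind == "lox") e$site$orientation <- e$orientation
        e
      }))
      elements[seq(i + 1L, j - 1L)] <- inner
    }
    construct(x$name, elements)
  }
}

#' Canonical state key of a construct
#'
#' Element id sequence plus orientations; used to deduplicate states during
#' event-graph exploration.
#' @param x a `construct`.
#' @return character scalar.
#' @export
construct_key <- function(x) {
  paste(vapply(x$elements, function(e) {
    paste(e$kind, e$id, e$orientation, sep = ":")
  }, character(1)), collapse = "|")
}

#' Exact distribution over stable recombination products
#'
#' Breadth-first exploration of the event graph under uniform event choice.
#' States with no available event are terminal. When the graph contains
#' inversion cycles that can still reach a terminal state, absorption
#' probabilities are obtained by exact rational Gaussian elimination; a cycle
#' from which no terminal state is reachable is reported as non-terminating
#' together with the cycling states.
#'
#' @param x a validated `construct`.
#' @return A `product_distribution`: list with `products` (list of terminal
#'   constructs), `probs` (exact [rational()] vector summing to 1) and `keys`
#'   (canonical state keys).
#' @export
stable_products <- function(x) {
  stopifnot(inherits(x, "construct"))
  states <- list()        # key -> list(construct, events, children keys)
  order_keys <- character(0)
  queue <- list(x)
  while (length(queue) > 0L) {
    s <- queue[[1L]]; queue <- queue[-1L]
    key <- construct_key(s)
    if (!is.null(states[[key]])) next
    ev <- enumerate_events(s)
    children <- character(0)
    child_constructs <- list()
    if (nrow(ev) > 0L) {
      for (k in seq_len(nrow(ev))) {
        child <- apply_event(s, ev[k, ])
        children <- c(children, construct_key(child))
        child_constructs[[k]] <- child
      }
    }
    states[[key]] <- list(construct = s, children = children)
    order_keys <- c(order_keys, key)
    for (child in child_constructs) queue[[length(queue) + 1L]] <- child
  }

  terminal <- vapply(states, function(s) length(s$children) == 0L, logical(1))
  term_keys <- names(states)[terminal]

  # reverse reachability from terminal states
  reach <- setNames(terminal, names(states))
  repeat {
    changed <- FALSE
    for (key in names(states)) {
      if (!reach[[key]] && any(reach[states[[key]]$children])) {
        reach[[key]] <- TRUE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  if (!all(reach)) {
    bad <- names(states)[!reach]
    stop(sprintf(
      "non-terminating recombination: no stable product reachable from state(s) %s",
      paste(bad, collapse = "; ")), call. = FALSE)
  }

  start_key <- construct_key(x)
  if (length(term_keys) == 1L && start_key %in% term_keys) {
    return(structure(list(products = list(x), probs = rational(1),
                          keys = start_key),
                     class = "product_distribution"))
  }

  trans_keys <- names(states)[!terminal]
  nt <- length(trans_keys)
  kt <- length(term_keys)
  # absorption probabilities B = (I - Q)^{-1} R via rational Gauss on [I-Q | R]
  aug <- vector("list", nt)
  for (r in seq_len(nt)) {
    row <- rational(rep(0, nt + kt))
    row[r] <- rational(1)
    children <- states[[trans_keys[r]]]$children
    w <- rational(1, length(children))
    for (child in children) {
      ci <- match(child, trans_keys)
      if (!is.na(ci)) {
        row[ci] <- row[ci] - w
      } else {
        ti <- match(child, term_keys)
        row[nt + ti] <- row[nt + ti] + w
      }
    }
    aug[[r]] <- row
  }
  for (col in seq_len(nt)) {
    piv <- NULL
    for (r in seq(col, nt)) {
      if (aug[[r]][col] != rational(0)) { piv <- r; break }
    }
    if (is.null(piv)) stop("singular event-graph system", call. = FALSE)
    if (piv != col) { tmp <- aug[[col]]; aug[[col]] <- aug[[piv]]; aug[[piv]] <- tmp }
    pval <- aug[[col]][col]
    aug[[col]] <- aug[[col]] / pval
    for (r in seq_len(nt)) {
      if (r != col && aug[[r]][col] != rational(0)) {
        aug[[r]] <- aug[[r]] - aug[[col]] * aug[[r]][col]
      }
    }
  }
  start_row <- match(start_key, trans_keys)
  probs <- aug[[start_row]][nt + seq_len(kt)]
  keep <- which(as.numeric(probs) > 0)
  structure(list(products = lapply(term_keys[keep],
                                   function(k) states[[k]]$construct),
                 probs = probs[keep],
                 keys = term_keys[keep]),
            class = "product_distribution")
}

#' @export
format.product_distribution <- function(x, ...) {
  paste0("<product_distribution over ", length(x$products), " stable product(s)>")
}

#' @export
print.product_distribution <- function(x, ...) {
  cat(format(x), "\n")
  for (i in seq_along(x$products)) {
    cat(sprintf("  %s  %s  markers: %s\n", format(x$probs[i]),
                format(x$products[[i]]),
                paste(construct_markers(x$products[[i]]), collapse = "+")))
  }
  invisible(x)
}

#' Marker-retention distribution of stable products
#'
#' Groups the stable products of [stable_products()] by retained marker set.
#'
#' @param pd a `product_distribution` (or a `construct`, which is resolved
#'   first).
#' @return A [pmf()] over sorted `+`-joined marker sets (e.g. `"mO"`,
#'   `"mC"`).
#' @export
marker_distribution <- function(pd) {
  if (inherits(pd, "construct")) pd <- stable_products(pd)
  stopifnot(inherits(pd, "product_distribution"))
  labels <- vapply(pd$products, function(p) .marker_class(construct_markers(p)),
                   character(1))
  .pmf_accumulate(labels, pd$probs)
}

#' Monte-Carlo walk over the recombination event graph
#'
#' Independent sanity check of [stable_products()]: repeatedly applies
#' uniformly chosen events until no event remains, and tallies terminal
#' marker sets. Uses the current RNG state; seed with [set.seed()] for
#' reproducibility.
#'
#' @param x a `construct`.
#' @param n_walks number of random walks.
#' @return table of terminal marker-set labels.
#' @export
walk_products <- function(x, n_walks = 1000L) {
  stopifnot(inherits(x, "construct"))
  # expand the reachable state graph once; each walk then only samples
  # uniformly among cached child states
  nodes <- new.env(parent = emptyenv())
  ensure <- function(con) {
    key <- construct_key(con)
    if (is.null(nodes[[key]])) {
      nodes[[key]] <- list()   # guard against re-entry on cycles
      ev <- enumerate_events(con)
      kids <- character(0)
      if (nrow(ev) > 0L) {
        kids <- vapply(seq_len(nrow(ev)), function(k) {
          ensure(apply_event(con, ev[k, ]))
        }, character(1))
      }
      nodes[[key]] <- list(label = .marker_class(construct_markers(con)),
                           children = kids)
    }
    key
  }
  start <- ensure(x)
  labels <- character(n_walks)
  for (w in seq_len(n_walks)) {
    key <- start
    repeat {
      node <- nodes[[key]]
      nk <- length(node$children)
      if (nk == 0L) break
      key <- node$children[[if (nk == 1L) 1L else sample.int(nk, 1L)]]
    }
    labels[w] <- nodes[[key]]$label
  }
  table(labels)
}
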