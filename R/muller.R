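# Nesting of mutations into clonal lineages for Muller plots. A mutation
# arising on the background of a preexisting mutation can never exceed
# the preexisting mutation's frequency and fluctuates in frequency with
# it; the assignment rule below operationalizes this dominance-plus-
# correlation criterion as a deterministic greedy procedure.

#' Assign mutations to nested clonal lineages
#'
#' Mutations are processed in descending order of maximum frequency
#' (ties broken by earlier origination, then lexicographic id). Each is
#' attached to the deepest already-placed lineage that dominates it —
#' child frequency at most parent frequency plus `eps` at every sampled
#' day — and with which its trajectory is positively correlated over
#' shared detected days; if no lineage qualifies it attaches to the root
#' (ancestral background). Low-frequency mutations (maximum below
#' `low_conf_max`) attached to the root carry a low-confidence flag, as
#' their placement cannot be resolved from frequencies alone.
#'
#' @param set a [trajectory_set()].
#' @param eps dominance tolerance (default 0.05, the precision scale of
#'   pool-seq frequency calls).
#' @param cor_min minimum Pearson correlation between child and candidate
#'   parent over shared detected days (default 0; the check passes
#'   automatically when fewer than 3 shared detected days exist or either
#'   trajectory is constant there).
#' @param low_conf_max maximum-frequency cutoff under which root
#'   placements are flagged low-confidence (default 0.2).
#' @return An object of class `"lineage_forest"`: list with `nodes`
#'   (mutation ids, root is `"root"`), `parent` (named character),
#'   `low_confidence` (named logical), the per-node frequency matrix and
#'   the day grid.
#' @export
#' @examples
#' ts <- trajectory_set("h", 1:3,
#'                      rbind(c(0.2, 0.6, 0.9), c(0.1, 0.4, 0.85)),
#'                      mutation_id = c("A", "B"))
#' assign_lineages(ts)$parent   # B nests inside A
assign_lineages <- function(set, eps = 0.05, cor_min = 0,
                            low_conf_max = 0.2) {
  stopifnot(inherits(set, "trajectory_set"))
  n <- n_mutations(set)
  ids <- set$meta$mutation_id
  if (n == 0L) {
    return(structure(list(nodes = character(0), parent = character(0),
                          low_confidence = logical(0),
                          freq = set$freq, days = set$days,
                          host_id = set$host_id, eps = eps),
                     class = "lineage_forest"))
  }
  g <- generations(set)
  maxf <- apply(set$freq, 1L, max)
  orig <- vapply(seq_len(n), function(i) {
    if (maxf[i] <= 0) return(max(g))
    t0 <- origination_time(set$freq[i, ], g, x0 = min(0.01, maxf[i]))
    if (is.na(t0)) max(g) else t0
  }, 0)
  ord <- order(-maxf, orig, ids)

  parent <- stats::setNames(rep(NA_character_, n), ids)
  depth <- stats::setNames(integer(n), ids)
  low_conf <- stats::setNames(logical(n), ids)
  placed <- character(0)

  dominates <- function(pi, ci) all(set$freq[ci, ] <= set$freq[pi, ] + eps)
  co_fluctuates <- function(pi, ci) {
    d <- set$freq[pi, ] > 0 & set$freq[ci, ] > 0
    if (sum(d) < 3L) return(TRUE)
    a <- set$freq[pi, d]; b <- set$freq[ci, d]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(TRUE)
    stats::cor(a, b) > cor_min
  }

  for (i in ord) {
    id <- ids[i]
    cand <- placed[vapply(placed, function(p) {
      pi <- match(p, ids)
      dominates(pi, i) && co_fluctuates(pi, i)
    }, TRUE)]
    if (length(cand)) {
      d <- depth[cand]
      best <- cand[d == max(d)]
      # among equally deep candidates prefer the most recently placed
      # (smallest maximum frequency): the most specific dominating lineage
      best <- best[length(best)]
      parent[id] <- best
      depth[id] <- depth[best] + 1L
    } else {
      parent[id] <- "root"
      depth[id] <- 1L
      low_conf[id] <- maxf[i] < low_conf_max
    }
    placed <- c(placed, id)
  }
  structure(list(nodes = ids, parent = parent, low_confidence = low_conf,
                 freq = set$freq, days = set$days, host_id = set$host_id,
                 eps = eps),
            class = "lineage_forest")
}

#' @export
print.lineage_forest <- function(x, ...) {
  cat(sprintf("Lineage forest: host %s, %d mutation(s)\n",
              x$host_id, length(x$nodes)))
  if (length(x$nodes)) {
    show <- data.frame(node = x$nodes, parent = unname(x$parent[x$nodes]),
                       low_confidence = unname(x$low_confidence[x$nodes]))
    print(show, row.names = FALSE)
  }
  invisible(x)
}

#' Muller-plot table of exclusive lineage abundances
#'
#' For each sampled day, the exclusive abundance of a lineage is its own
#' frequency minus the summed frequencies of its child lineages; the root
#' (ancestral background, frequency 1) absorbs the remainder. When the
#' children of a node sum to more than the node's frequency by at most the
#' forest's `eps` tolerance, the children are proportionally rescaled for
#' that day (with a warning); a larger violation is an inconsistency error
#' naming the day and nodes. Per day the abundances are non-negative and
#' sum to 1.
#'
#' @param forest a `"lineage_forest"` from [assign_lineages()].
#' @return long-format data frame with columns `day`, `lineage`
#'   (`"root"` for the ancestral background) and `abundance`.
#' @export
muller_table <- function(forest) {
  stopifnot(inherits(forest, "lineage_forest"))
  days <- forest$days
  ids <- forest$nodes
  nodes <- c("root", ids)
  freq <- rbind(rep(1, length(days)), forest$freq)
  rownames(freq) <- nodes
  kids <- split(ids, forest$parent[ids])
  # depth-ordered pass (parents first) so rescaled child frequencies
  # propagate before the children's own exclusives are formed
  depth <- stats::setNames(integer(length(nodes)), nodes)
  for (id in ids) {
    d <- 1L; p <- forest$parent[[id]]
    while (p != "root") { d <- d + 1L; p <- forest$parent[[p]] }
    depth[id] <- d
  }
  for (nd in nodes[order(depth[nodes])]) {
    ch <- kids[[nd]]
    if (is.null(ch) || length(ch) == 0L) next
    for (j in seq_along(days)) {
      tot <- sum(freq[ch, j])
      if (tot > freq[nd, j] + forest$eps)
        stop(sprintf(
          "lineage inconsistency at day %s: children of %s sum to %.3f > %.3f",
          format(days[j]), nd, tot, freq[nd, j]))
      if (tot > freq[nd, j]) {
        warning(sprintf(
          "children of %s rescaled at day %s (sum %.3f clipped to %.3f)",
          nd, format(days[j]), tot, freq[nd, j]))
        freq[ch, j] <- freq[ch, j] * freq[nd, j] / tot
      }
    }
  }
  excl <- freq
  for (nd in nodes) {
    ch <- kids[[nd]]
    if (!is.null(ch) && length(ch))
      excl[nd, ] <- freq[nd, ] - colSums(freq[ch, , drop = FALSE])
  }
  # column-major order of excl matches (all nodes at day 1, day 2, ...)
  data.frame(
    day = rep(days, each = length(nodes)),
    lineage = rep(nodes, times = length(days)),
    abundance = as.vector(excl),
    stringsAsFactors = FALSE
  )
}

#' Stacked-area Muller plot of exclusive lineage abundances
#'
#' Thin base-graphics presentation helper over [muller_table()].
#'
#' @param forest a `"lineage_forest"`.
#' @param col fill colours, recycled over lineages.
#' @param ... passed to [graphics::plot()].
#' @return the muller table, invisibly.
#' @export
plot_muller <- function(forest, col = grDevices::hcl.colors(
  max(2L, length(forest$nodes) + 1L), "Spectral"), ...) {
  tab <- muller_table(forest)
  days <- sort(unique(tab$day))
  lins <- unique(tab$lineage)
  m <- matrix(tab$abundance, nrow = length(lins),
              dimnames = list(lins, NULL))
  cum <- apply(m, 2L, cumsum)
  graphics::plot(range(days), c(0, 1), type = "n", xlab = "day",
                 ylab = "abundance", ...)
  col <- rep_len(col, length(lins))
  lower <- rep(0, length(days))
  for (k in seq_along(lins)) {
    upper <- cum[k, ]
    graphics::polygon(c(days, rev(days)), c(lower, rev(upper)),
                      col = col[k], border = NA)
    lower <- upper
  }
  invisible(tab)
}
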