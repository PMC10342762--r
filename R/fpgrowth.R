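# FP-growth frequent-itemset mining on binary transaction matrices.
# A compressed prefix tree (FP-tree) is built over frequency-ordered items;
# itemsets are mined recursively from conditional pattern bases, so no
# candidate generation is needed.

# Build an FP-tree from integer-coded paths (already filtered to frequent
# items and sorted by the tree's item order). Nodes live in parallel vectors;
# children are looked up through an environment keyed by "parent|item".
.fp_build <- function(paths, weights) {
  item <- integer(1); count <- numeric(1); parent <- integer(1) # node 1 = root
  item[1] <- 0L; count[1] <- 0; parent[1] <- 0L
  kids <- new.env(hash = TRUE, parent = emptyenv())
  header <- list()
  for (p in seq_along(paths)) {
    path <- paths[[p]]
    w <- weights[p]
    node <- 1L
    for (it in path) {
      key <- paste0(node, "|", it)
      child <- kids[[key]]
      if (is.null(child)) {
        child <- length(item) + 1L
        item[child] <- it; count[child] <- 0; parent[child] <- node
        kids[[key]] <- child
        hk <- as.character(it)
        header[[hk]] <- c(header[[hk]], child)
      }
      count[child] <- count[child] + w
      node <- child
    }
  }
  list(item = item, count = count, parent = parent, header = header)
}

# Recursive mining of weighted paths: filter to conditionally frequent items,
# build the conditional FP-tree, emit each frequent item with the suffix, and
# recurse on its conditional pattern base.
.fp_mine <- function(paths, weights, min_count, suffix, acc) {
  if (length(paths) == 0L) return(acc)
  tallies <- tapply(rep(weights, lengths(paths)), unlist(paths), sum)
  freq <- as.integer(names(tallies))[tallies >= min_count]
  if (length(freq) == 0L) return(acc)
  tot <- tallies[as.character(freq)]
  ord <- freq[order(-tot, freq)] # descending frequency, ties by item id
  rank <- integer(max(ord)); rank[ord] <- seq_along(ord)
  fpaths <- lapply(paths, function(p) {
    p <- p[p %in% ord]
    p[order(rank[p])]
  })
  keep <- lengths(fpaths) > 0L
  tree <- .fp_build(fpaths[keep], weights[keep])
  for (it in rev(ord)) { # least frequent first
    hk <- as.character(it)
    nodes <- tree$header[[hk]]
    supp <- sum(tree$count[nodes])
    itemset <- c(it, suffix)
    acc[[length(acc) + 1L]] <- list(items = itemset, count = supp)
    # conditional pattern base: prefix path of every node carrying this item
    cpaths <- list(); cweights <- numeric(0)
    for (nd in nodes) {
      pth <- integer(0)
      up <- tree$parent[nd]
      while (up != 0L && up != 1L) {
        pth <- c(tree$item[up], pth)
        up <- tree$parent[up]
      }
      if (length(pth) > 0L) {
        cpaths[[length(cpaths) + 1L]] <- pth
        cweights <- c(cweights, tree$count[nd])
      }
    }
    acc <- .fp_mine(cpaths, cweights, min_count, itemset, acc)
  }
  acc
}

#' Frequent-itemset mining by FP-growth
#'
#' Finds all itemsets whose support (fraction of transactions containing every
#' item of the set) is at least `min_support`, with exact support counts,
#' using the FP-growth algorithm on a compressed FP-tree. Output order is
#' deterministic: support descending, then lexicographic on the item names.
#'
#' @param transactions Binary (0/1 or logical) matrix, rows = transactions,
#'   named columns = items.
#' @param min_support Minimum support as a fraction in (0, 1].
#' @return Data frame with list-column `items` (sorted item names), `itemset`
#'   (comma-joined string), `count`, and `support`. Empty input yields an
#'   empty result.
#' @examples
#' m <- rbind(c(1, 1), c(1, 1), c(1, 0))
#' colnames(m) <- c("A", "B")
#' fp_growth(m, 0.6)
#' @export
fp_growth <- function(transactions, min_support) {
  if (!is.numeric(min_support) || min_support <= 0 || min_support > 1) {
    stop("min_support must be in (0, 1]")
  }
  m <- as.matrix(transactions) * 1
  empty <- data.frame(itemset = character(0), count = numeric(0),
                      support = numeric(0), stringsAsFactors = FALSE)
  empty$items <- list()
  if (nrow(m) == 0L || ncol(m) == 0L) return(empty)
  if (is.null(colnames(m))) colnames(m) <- paste0("item", seq_len(ncol(m)))
  n <- nrow(m)
  min_count <- min_support * n - 1e-9
  paths <- apply(m > 0, 1L, which, simplify = FALSE)
  acc <- .fp_mine(paths, rep(1, n), min_count, integer(0), list())
  if (length(acc) == 0L) return(empty)
  item_names <- colnames(m)
  sets <- lapply(acc, function(e) sort(item_names[e$items]))
  counts <- vapply(acc, function(e) e$count, numeric(1))
  res <- data.frame(itemset = vapply(sets, paste, character(1), collapse = ","),
                    count = counts, support = counts / n,
                    stringsAsFactors = FALSE)
  res$items <- sets
  ord <- order(-res$count, res$itemset)
  res <- res[ord, , drop = FALSE]
  rownames(res) <- NULL
  res
}
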