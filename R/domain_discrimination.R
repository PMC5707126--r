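# Domain-level discrimination: catalog hit counts are binned by retroviral
# domain type, normalized by HQ reads, log2-transformed and centered along
# the domain axis, specimens are hierarchically clustered (1 - Pearson
# correlation, average linkage), the dendrogram is cut at its root into two
# clusters, and group separation is tested with the two-tailed Fisher exact
# test.

#' Domain-binned hit rates
#'
#' Per (domain type, specimen): the sum of catalog entry counts of that
#' domain divided by the specimen's HQ read count.
#'
#' @param counts entry x specimen count matrix (comprehensive counts by
#'   default in the pipeline).
#' @param entry_domains named character vector mapping entry code to domain
#'   type (or a catalog table).
#' @param hq_counts named HQ read counts per specimen.
#' @return domain x specimen matrix of raw hit rates.
#' @export
domain_hit_rates <- function(counts, entry_domains, hq_counts) {
  if (is.data.frame(entry_domains)) {
    entry_domains <- stats::setNames(entry_domains$domain_type,
                                     entry_domains$code)
  }
  missing <- setdiff(rownames(counts), names(entry_domains))
  if (length(missing)) {
    stop("entries missing from the domain map: ",
         paste(utils::head(missing, 3), collapse = ", "))
  }
  dom <- entry_domains[rownames(counts)]
  agg <- rowsum(counts, group = dom)
  hq <- hq_counts[colnames(counts)]
  if (any(is.na(hq))) stop("HQ counts missing for some specimens")
  sweep(agg, 2, as.numeric(hq), "/")
}

#' Log2 transform and center along the domain axis
#'
#' `v = log2(rate + pseudocount)`, then each domain row is mean-centered
#' across specimens, so rows sum to zero.
#'
#' @param raw domain x specimen matrix of hit rates.
#' @param pseudocount positive stabilizer added before the log; the
#'   pipeline defaults it to `0.5 / median(hq)` (half a hit).
#' @return centered matrix (a "domain profile").
#' @export
log2_center <- function(raw, pseudocount) {
  stopifnot(length(pseudocount) == 1L, pseudocount > 0)
  v <- log2(raw + pseudocount)
  sweep(v, 1, rowMeans(v), "-")
}

#' Hierarchically cluster specimens on their domain profile
#'
#' Agglomerative clustering of specimen columns with distance
#' `d = 1 - Pearson r` over domain values and average linkage (UPGMA).
#' Merge ties are broken by the smallest pair index in input order, so the
#' result is deterministic. Columns with zero variance get correlation 0
#' (distance 1) against everything, with a warning.
#'
#' @param profile domain x specimen matrix from [log2_center()].
#' @return an object of class `hclust` (merge/height/order/labels).
#' @export
cluster_specimens <- function(profile) {
  n <- ncol(profile)
  stopifnot(n >= 2L, nrow(profile) >= 2L)
  sds <- apply(profile, 2, stats::sd)
  if (any(sds == 0)) {
    warning("zero-variance specimen column(s); correlations set to 0")
  }
  cm <- suppressWarnings(stats::cor(profile))
  cm[!is.finite(cm)] <- 0
  d <- 1 - cm
  diag(d) <- 0
  # UPGMA agglomeration with deterministic tie-breaking
  active <- seq_len(n)
  sizes <- rep(1L, n)
  id <- -seq_len(n)              # hclust convention: negatives = leaves
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  members <- as.list(seq_len(n))
  for (step in seq_len(n - 1L)) {
    k <- length(active)
    best <- c(NA, NA); bestd <- Inf
    for (i in seq_len(k - 1L)) {
      for (j in seq(i + 1L, k)) {
        dij <- d[active[i], active[j]]
        if (dij < bestd - 1e-12) {
          bestd <- dij; best <- c(i, j)
        }
      }
    }
    i <- best[1]; j <- best[2]
    ai <- active[i]; aj <- active[j]
    merge[step, ] <- sort(c(id[ai], id[aj]))
    height[step] <- bestd
    # average linkage update (weighted by cluster sizes = UPGMA)
    ni <- sizes[ai]; nj <- sizes[aj]
    for (o in active) {
      if (o == ai || o == aj) next
      d[ai, o] <- d[o, ai] <- (ni * d[ai, o] + nj * d[aj, o]) / (ni + nj)
    }
    sizes[ai] <- ni + nj
    id[ai] <- step
    members[[ai]] <- c(members[[ai]], members[[aj]])
    active <- active[-j]
  }
  order_leaves <- function(node) {
    if (node < 0) return(-node)
    c(order_leaves(merge[node, 1]), order_leaves(merge[node, 2]))
  }
  structure(list(merge = merge, height = height,
                 order = order_leaves(n - 1L),
                 labels = colnames(profile), method = "average",
                 dist.method = "1-pearson",
                 call = match.call()),
            class = "hclust")
}

hclust_leaves <- function(hc, node) {
  if (node < 0) return(-node)
  c(hclust_leaves(hc, hc$merge[node, 1]),
    hclust_leaves(hc, hc$merge[node, 2]))
}

#' Cut the dendrogram at its root and test group separation
#'
#' The final merge defines the two dominant clusters. A 2x2 contingency
#' table (group x side) is built restricted to the two groups under test
#' (other groups' specimens are ignored) and a two-tailed Fisher exact p is
#' attached. The "left" cluster is the side holding more members of the
#' first group under test (presentation only; the p-value is
#' label-invariant).
#'
#' @param hc `hclust` object from [cluster_specimens()].
#' @param design design table (`specimen_id`, `group`).
#' @param groups_to_test character vector of the two groups compared.
#' @return list with class `hervex_cluster_split`: `left_members`,
#'   `right_members` (all specimens, by side), `contingency` (2x2 matrix),
#'   `fisher_p`, `dendrogram`.
#' @export
split_and_test <- function(hc, design,
                           groups_to_test = c("demyelination", "control")) {
  stopifnot(inherits(hc, "hclust"), length(groups_to_test) == 2L)
  n <- length(hc$labels)
  root <- nrow(hc$merge)
  side_a <- hc$labels[hclust_leaves(hc, hc$merge[root, 1])]
  side_b <- hc$labels[hclust_leaves(hc, hc$merge[root, 2])]
  grp <- stats::setNames(design$group, design$specimen_id)
  g1 <- groups_to_test[1]; g2 <- groups_to_test[2]
  in_a <- sum(grp[side_a] == g1, na.rm = TRUE)
  in_b <- sum(grp[side_b] == g1, na.rm = TRUE)
  if (in_a + in_b == 0L || sum(grp[c(side_a, side_b)] == g2,
                               na.rm = TRUE) == 0L) {
    stop("a group under test is absent from the dendrogram")
  }
  left <- if (in_a >= in_b) side_a else side_b
  right <- if (in_a >= in_b) side_b else side_a
  tab <- matrix(c(sum(grp[left] == g1, na.rm = TRUE),
                  sum(grp[right] == g1, na.rm = TRUE),
                  sum(grp[left] == g2, na.rm = TRUE),
                  sum(grp[right] == g2, na.rm = TRUE)),
                nrow = 2, byrow = TRUE,
                dimnames = list(groups_to_test, c("left", "right")))
  ft <- fisher_exact_2x2(tab)
  structure(list(left_members = left, right_members = right,
                 contingency = tab, fisher_p = ft$p_value,
                 dendrogram = hc),
            class = "hervex_cluster_split")
}

#' @export
print.hervex_cluster_split <- function(x, ...) {
  cat("Cluster split at dendrogram root\n")
  print(x$contingency)
  cat(sprintf("Two-tailed Fisher exact p = %.4g\n", x$fisher_p))
  invisible(x)
}
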