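# Independent oracles and small fixture builders used across the suite.

# Brute-force UPGMA: recomputes every inter-cluster distance from the
# original pairwise matrix at each of the n-1 merges (O(n^3)).
upgma_oracle <- function(x) {
  d <- as.matrix(dist(x))
  clusters <- as.list(seq_len(nrow(as.matrix(x))))
  heights <- numeric(0)
  partitions <- list()
  while (length(clusters) > 1) {
    best <- NULL
    bestd <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_len(i - 1)) {
        dd <- mean(d[clusters[[i]], clusters[[j]]])
        if (dd < bestd) {
          bestd <- dd
          best <- c(j, i)
        }
      }
    }
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    clusters <- clusters[-best]
    clusters[[length(clusters) + 1]] <- merged
    heights <- c(heights, bestd)
    partitions[[length(partitions) + 1]] <- clusters
  }
  list(heights = heights, partitions = partitions)
}

# Canonical string form of a partition (list of integer clusters).
partition_key <- function(clusters) {
  paste(sort(vapply(clusters, function(cl)
    paste(sort(cl), collapse = ","), character(1))), collapse = "|")
}

# Partition of 1..n implied by an hclust object after k merges.
hclust_partition <- function(hc, k_merges) {
  n <- length(hc$order)
  memb <- cutree(hc, k = n - k_merges)
  unname(split(seq_len(n), memb))
}

# Brute-force mean distance to centroid from raw coordinates.
mean_distance_oracle <- function(larvae) {
  pts <- which(larvae == 1L, arr.ind = TRUE)
  cx <- sum(pts[, 1]) / nrow(pts)
  cy <- sum(pts[, 2]) / nrow(pts)
  s <- 0
  for (i in seq_len(nrow(pts)))
    s <- s + sqrt((pts[i, 1] - cx)^2 + (pts[i, 2] - cy)^2)
  unname(s / nrow(pts))
}

# Constant strain x key probability matrix.
const_mat <- function(value, cols, strains = c("SS", "RR")) {
  matrix(value, nrow = length(strains), ncol = length(cols),
         dimnames = list(strains, as.character(cols)))
}

# Degenerate parameters: everything survives, stays on plant, feeds.
all_on_fed_params <- function(intervals = c(6, 12, 18, 24),
                              varieties = c("BT_WS", "NONBT")) {
  bioassay_params(
    survival_prob = const_mat(1, intervals),
    on_plant_prob = const_mat(1, intervals),
    fed_given_on_prob = const_mat(1, varieties),
    fed_given_off_prob = const_mat(0, varieties))
}

# One-row bioassay table from explicit counts.
bioassay_row <- function(on_fed, on_notfed, off_fed, off_notfed,
                         unrecovered,
                         released = on_fed + on_notfed + off_fed +
                           off_notfed + unrecovered) {
  data.frame(block = 1L, strain = "SS", variety = "BT_WS", interval_h = 6,
             released = released, on_fed = on_fed, on_notfed = on_notfed,
             off_fed = off_fed, off_notfed = off_notfed,
             unrecovered = unrecovered, stringsAsFactors = FALSE)
}
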