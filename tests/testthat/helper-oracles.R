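# Independent brute-force oracles used across the suite. These deliberately
# share no code with the package internals they check.

# all permutations of a vector (n <= 7 in the suite)
all_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  do.call(c, lapply(seq_along(v), function(i) {
    lapply(all_perms(v[-i]), function(p) c(v[i], p))
  }))
}

# exhaustive element-respecting minimum RMSD between two atom tables
brute_force_rmsd <- function(a, b) {
  a <- a[a$element != "H", ]; b <- b[b$element != "H", ]
  stopifnot(nrow(a) == nrow(b))
  xa <- cbind(a$x, a$y, a$z); xb <- cbind(b$x, b$y, b$z)
  best <- Inf
  for (p in all_perms(seq_len(nrow(b)))) {
    if (!all(a$element == b$element[p])) next
    ss <- sum((xa - xb[p, , drop = FALSE])^2)
    if (ss < best) best <- ss
  }
  sqrt(best / nrow(a))
}

# exhaustive minimum of a rectangular assignment cost matrix
brute_force_lsap <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  best <- Inf
  for (p in all_perms(seq_len(m))) {
    pc <- p[seq_len(n)]
    cst <- sum(cost[cbind(seq_len(n), pc)])
    if (cst < best) best <- cst
  }
  best
}

# independent Borda aggregation: sum over metrics of (n - rank), average ties
brute_force_borda <- function(score_mat, lower_better) {
  n <- nrow(score_mat)
  pts <- numeric(n)
  for (k in seq_len(ncol(score_mat))) {
    s <- score_mat[, k]
    if (!lower_better[k]) s <- -s
    pts <- pts + (n - rank(s, ties.method = "average"))
  }
  pts
}

# naive agglomerative clustering on a distance matrix: repeatedly merge the
# two closest clusters under the given linkage until the closest pair
# exceeds the cutoff; returns cluster membership
naive_agglomerate <- function(d, linkage, cutoff) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  link_dist <- function(ci, cj) {
    vals <- d[ci, cj, drop = FALSE]
    switch(linkage, complete = max(vals), single = min(vals),
           average = mean(vals))
  }
  repeat {
    if (length(clusters) == 1) break
    best <- c(NA, NA); bestd <- Inf
    for (i in seq_len(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        dd <- link_dist(clusters[[i]], clusters[[j]])
        if (dd < bestd) { bestd <- dd; best <- c(i, j) }
      }
    }
    if (bestd > cutoff) break
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  labels <- integer(n)
  for (k in seq_along(clusters)) labels[clusters[[k]]] <- k
  labels
}

# partition equality irrespective of label numbering
same_partition <- function(l1, l2) {
  identical(outer(l1, l1, "=="), outer(l2, l2, "=="))
}

# random pose with the given element vector, coordinates ~ U(-span, span)
random_pose <- function(elements, span = 3) {
  as_atoms(data.frame(element = elements,
                      x = runif(length(elements), -span, span),
                      y = runif(length(elements), -span, span),
                      z = runif(length(elements), -span, span)))
}

rotate_z <- function(atoms, degrees) {
  th <- degrees * pi / 180
  x0 <- atoms$x
  atoms$x <- x0 * cos(th) - atoms$y * sin(th)
  atoms$y <- x0 * sin(th) + atoms$y * cos(th)
  atoms
}

translate <- function(atoms, v) {
  atoms$x <- atoms$x + v[1]; atoms$y <- atoms$y + v[2]
  atoms$z <- atoms$z + v[3]
  atoms
}
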