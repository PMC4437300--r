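# Independent oracles and small fixture builders shared across test files.

# Exhaustive Ward oracle: at every step evaluate every candidate merge's
# ESS increase directly from cluster members (no Lance-Williams shortcut),
# with the same oldest-pair tie-break as the implementation.
ess_of <- function(x, members) {
  if (length(members) == 1L) return(0)
  sub <- x[members, , drop = FALSE]
  ctr <- colMeans(sub)
  sum(sweep(sub, 2, ctr)^2)
}

ward_oracle <- function(x) {
  n <- nrow(x)
  clusters <- as.list(seq_len(n))
  created <- seq_len(n)                 # creation order for tie-breaking
  merges <- list()
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- Inf; bi <- 0L; bj <- 0L
    ord <- order(created)
    for (a in seq_len(length(clusters) - 1L)) {
      for (b in (a + 1L):length(clusters)) {
        i <- ord[a]; j <- ord[b]
        d <- ess_of(x, c(clusters[[i]], clusters[[j]])) -
          ess_of(x, clusters[[i]]) - ess_of(x, clusters[[j]])
        if (d < best - 1e-12) { best <- d; bi <- i; bj <- j }
      }
    }
    merges[[length(merges) + 1L]] <- sort(c(clusters[[bi]], clusters[[bj]]))
    heights <- c(heights, best)
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    created[bi] <- min(created[bi], created[bj])
    clusters[[bj]] <- NULL
    created <- created[-bj]
  }
  list(merges = merges, heights = heights)
}

# partition of 1..n implied by the first n-k oracle merges
oracle_partition <- function(x, k) {
  n <- nrow(x)
  orc <- ward_oracle(x)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (m in seq_len(n - k)) {
    ids <- orc$merges[[m]]
    r <- find(ids[1])
    for (i in ids[-1]) parent[find(i)] <- r
  }
  vapply(seq_len(n), find, integer(1))
}

# do two label vectors describe the same partition?
same_partition <- function(a, b) {
  all(outer(a, a, "==") == outer(b, b, "=="))
}

# best-matching two-cluster label agreement
label_agreement <- function(labels, truth) {
  a <- mean((labels == labels[1]) == (truth == truth[1]))
  max(a, 1 - a)
}

# hand-built spike train (bypasses trace generation)
make_train <- function(times_ms, amp_pa = 100, step_dur_s = 1) {
  structure(list(times_ms = times_ms, amp_pa = amp_pa, step_dur_s = step_dur_s),
            class = "spike_train")
}

# spheroid surface by numerical surface-of-revolution integration
spheroid_area_numeric <- function(minor_um, major_um) {
  a <- major_um / 2; b <- minor_um / 2
  f <- function(x) {
    y <- b * sqrt(pmax(0, 1 - x^2 / a^2))
    dy <- -b * x / (a^2 * sqrt(pmax(1e-300, 1 - x^2 / a^2)))
    2 * pi * y * sqrt(1 + dy^2)
  }
  stats::integrate(f, -a, a, rel.tol = 1e-10)$value
}
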