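# Brute-force oracles and small fixture builders shared across tests. The
# oracles deliberately use naive enumeration (nested loops, BFS) so they are
# independent of the vectorized implementations they check.

img3 <- function(arr, spacing = 1) image_volume(arr, spacing)

msk3 <- function(arr, spacing = 1, role = "tumor") roi_mask(arr, spacing, role = role)

# a discretized ROI fixture with exactly the given integer levels
# (NA = outside the ROI); built directly so tests control the level map
droi_from_levels <- function(lv, spacing = 1, n_bins = NULL) {
  storage.mode(lv) <- "integer"
  mask <- !is.na(lv)
  if (is.null(n_bins)) n_bins <- max(2L, max(lv, na.rm = TRUE))
  structure(list(levels = lv, mask = mask, n_bins = as.integer(n_bins),
                 bin_edges = seq(0.5, n_bins + 0.5, by = 1),
                 raw = as.numeric(lv[mask]), spacing = rep(spacing, 3),
                 role = "tumor"),
            class = "discretized_roi")
}

random_droi <- function(seed, dims = c(5, 5, 4), n_levels = 4, p_roi = 0.7) {
  set.seed(seed)
  lv <- array(sample(seq_len(n_levels), prod(dims), replace = TRUE), dims)
  lv[array(runif(prod(dims)) > p_roi, dims)] <- NA
  if (all(is.na(lv))) lv[1, 1, 1] <- 1L
  droi_from_levels(lv, n_bins = n_levels)
}

offsets_oracle <- function(mode) {
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (mode == "2.5D") offs <- offs[offs[, 3] == 0, , drop = FALSE]
  offs
}

oracle_glcm <- function(lv, d, n_levels) {
  dm <- dim(lv)
  P <- matrix(0, n_levels, n_levels)
  for (i in seq_len(dm[1])) for (j in seq_len(dm[2])) for (k in seq_len(dm[3])) {
    if (is.na(lv[i, j, k])) next
    w <- c(i, j, k) + d
    if (any(w < 1) || any(w > dm)) next
    if (is.na(lv[w[1], w[2], w[3]])) next
    a <- lv[i, j, k]; b <- lv[w[1], w[2], w[3]]
    P[a, b] <- P[a, b] + 1
    P[b, a] <- P[b, a] + 1
  }
  P
}

oracle_glrlm <- function(lv, d, n_levels) {
  dm <- dim(lv)
  runs <- list()
  inb <- function(v) all(v >= 1) && all(v <= dm)
  val <- function(v) lv[v[1], v[2], v[3]]
  for (i in seq_len(dm[1])) for (j in seq_len(dm[2])) for (k in seq_len(dm[3])) {
    v <- c(i, j, k)
    if (is.na(val(v))) next
    prev <- v - d
    if (inb(prev) && !is.na(val(prev)) && val(prev) == val(v)) next  # not a run start
    len <- 1
    nxt <- v + d
    while (inb(nxt) && !is.na(val(nxt)) && val(nxt) == val(v)) {
      len <- len + 1
      nxt <- nxt + d
    }
    runs[[length(runs) + 1]] <- c(val(v), len)
  }
  rm_ <- do.call(rbind, runs)
  P <- matrix(0, n_levels, max(rm_[, 2]))
  for (r in seq_len(nrow(rm_))) P[rm_[r, 1], rm_[r, 2]] <- P[rm_[r, 1], rm_[r, 2]] + 1
  P
}

oracle_glszm <- function(lv, mode, n_levels) {
  dm <- dim(lv)
  offs <- offsets_oracle(mode)
  seen <- array(FALSE, dm)
  zones <- list()
  for (i in seq_len(dm[1])) for (j in seq_len(dm[2])) for (k in seq_len(dm[3])) {
    if (is.na(lv[i, j, k]) || seen[i, j, k]) next
    l <- lv[i, j, k]
    queue <- list(c(i, j, k)); seen[i, j, k] <- TRUE; sz <- 0
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]; sz <- sz + 1
      for (r in seq_len(nrow(offs))) {
        w <- v + offs[r, ]
        if (any(w < 1) || any(w > dm)) next
        if (seen[w[1], w[2], w[3]] || is.na(lv[w[1], w[2], w[3]])) next
        if (lv[w[1], w[2], w[3]] == l) {
          seen[w[1], w[2], w[3]] <- TRUE
          queue <- c(queue, list(w))
        }
      }
    }
    zones[[length(zones) + 1]] <- c(l, sz)
  }
  zm <- do.call(rbind, zones)
  P <- matrix(0, n_levels, max(zm[, 2]))
  for (r in seq_len(nrow(zm))) P[zm[r, 1], zm[r, 2]] <- P[zm[r, 1], zm[r, 2]] + 1
  P
}

oracle_gldm <- function(lv, mode, n_levels) {
  dm <- dim(lv)
  offs <- offsets_oracle(mode)
  recs <- list()
  for (i in seq_len(dm[1])) for (j in seq_len(dm[2])) for (k in seq_len(dm[3])) {
    if (is.na(lv[i, j, k])) next
    dep <- 1  # center voxel counted
    for (r in seq_len(nrow(offs))) {
      w <- c(i, j, k) + offs[r, ]
      if (any(w < 1) || any(w > dm)) next
      if (!is.na(lv[w[1], w[2], w[3]]) && lv[w[1], w[2], w[3]] == lv[i, j, k])
        dep <- dep + 1
    }
    recs[[length(recs) + 1]] <- c(lv[i, j, k], dep)
  }
  rm_ <- do.call(rbind, recs)
  P <- matrix(0, n_levels, max(rm_[, 2]))
  for (r in seq_len(nrow(rm_))) P[rm_[r, 1], rm_[r, 2]] <- P[rm_[r, 1], rm_[r, 2]] + 1
  P
}

oracle_ngtdm <- function(lv, mode, n_levels) {
  dm <- dim(lv)
  offs <- offsets_oracle(mode)
  n <- numeric(n_levels); s <- numeric(n_levels); nvp <- 0
  for (i in seq_len(dm[1])) for (j in seq_len(dm[2])) for (k in seq_len(dm[3])) {
    if (is.na(lv[i, j, k])) next
    nb <- c()
    for (r in seq_len(nrow(offs))) {
      w <- c(i, j, k) + offs[r, ]
      if (any(w < 1) || any(w > dm)) next
      if (!is.na(lv[w[1], w[2], w[3]])) nb <- c(nb, lv[w[1], w[2], w[3]])
    }
    if (length(nb) == 0) next
    l <- lv[i, j, k]
    n[l] <- n[l] + 1
    s[l] <- s[l] + abs(l - mean(nb))
    nvp <- nvp + 1
  }
  list(n = n, s = s, p = if (nvp > 0) n / nvp else n, n_valid = nvp)
}

oracle_cindex <- function(score, time, event) {
  num <- 0; den <- 0
  n <- length(time)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (time[i] < time[j] && event[i] == 1) {
      den <- den + 1
      if (score[i] > score[j]) num <- num + 1
      else if (score[i] == score[j]) num <- num + 0.5
    }
  }
  if (den == 0) return(NA_real_)
  num / den
}

# exhaustive two-sided signed-rank p over all 2^n sign assignments
oracle_wilcoxon <- function(a, b) {
  d <- (a - b)
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  Wall <- numeric(2^n)
  for (m in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(m))[seq_len(n)]
    Wall[m + 1] <- sum(r[bits == 1])
  }
  min(1, 2 * min(mean(Wall <= W), mean(Wall >= W)))
}

oracle_pareto <- function(points) {
  n <- nrow(points)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    dominates <- points$ccc[j] >= points$ccc[i] && points$cindex[j] >= points$cindex[i] &&
      (points$ccc[j] > points$ccc[i] || points$cindex[j] > points$cindex[i])
    if (dominates) { keep[i] <- FALSE; break }
  }
  points[keep, , drop = FALSE]
}

# small censored survival fixture
random_surv <- function(seed, n, rate = 0.05, cens = 30) {
  set.seed(seed)
  et <- rexp(n, rate)
  ct <- runif(n, 0, cens)
  list(time = pmin(et, ct), event = as.integer(et <= ct), score = rnorm(n))
}
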