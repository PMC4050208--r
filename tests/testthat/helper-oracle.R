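# Brute-force alignment oracles, independent of the package's DP kernels.
# Global and local optima are found by enumerating every possible alignment
# (as a monotone path of diag/up/left ops) and scoring it directly; the LCS
# oracle enumerates subsequences. Path sets depend only on the two lengths,
# so they are enumerated once per (m, n) and cached in flattened form.

.oracle_cache <- new.env(parent = emptyenv())

# every alignment of an m-residue vs n-residue sequence, as op vectors
# (1 = diag, 2 = up/consume a, 3 = left/consume b)
oracle_paths <- function(m, n) {
  key <- sprintf("p:%d,%d", m, n)
  if (!is.null(.oracle_cache[[key]])) return(.oracle_cache[[key]])
  res <- if (m == 0L && n == 0L) list(integer(0)) else {
    acc <- list()
    if (m > 0L && n > 0L)
      acc <- c(acc, lapply(oracle_paths(m - 1L, n - 1L), function(p) c(p, 1L)))
    if (m > 0L)
      acc <- c(acc, lapply(oracle_paths(m - 1L, n), function(p) c(p, 2L)))
    if (n > 0L)
      acc <- c(acc, lapply(oracle_paths(m, n - 1L), function(p) c(p, 3L)))
    acc
  }
  .oracle_cache[[key]] <- res
  res
}

# flattened per-(m,n) summary of all paths: indices of the diagonal
# (substitution) positions plus each path's gap-position and gap-run counts
oracle_struct <- function(m, n) {
  key <- sprintf("s:%d,%d", m, n)
  if (!is.null(.oracle_cache[[key]])) return(.oracle_cache[[key]])
  paths <- oracle_paths(m, n)
  dia <- vector("list", length(paths)); dib <- vector("list", length(paths))
  n_gap <- integer(length(paths)); n_runs <- integer(length(paths))
  for (i in seq_along(paths)) {
    p <- paths[[i]]
    ia <- cumsum(p != 3L); ib <- cumsum(p != 2L)
    d <- p == 1L
    dia[[i]] <- ia[d]; dib[[i]] <- ib[d]
    n_gap[i] <- sum(!d)
    r <- rle(p)
    n_runs[i] <- sum(r$values != 1L)
  }
  nd <- lengths(dia)
  s <- list(dia = unlist(dia), dib = unlist(dib), ndiag = nd,
            ends = cumsum(nd), n_gap = n_gap, n_runs = n_runs)
  .oracle_cache[[key]] <- s
  s
}

# best global score over every enumerated alignment; linear gap cost
# `gap` per gapped position and affine cost open + k * ext per gap run
oracle_global <- function(a, b, match, mismatch, gap, open, ext) {
  st <- oracle_struct(length(a), length(b))
  v <- ifelse(a[st$dia] == b[st$dib], match, mismatch)
  cs <- c(0, cumsum(v))
  sums <- cs[st$ends + 1L] - cs[st$ends - st$ndiag + 1L]
  c(linear = max(sums - gap * st$n_gap),
    affine = max(sums - open * st$n_runs - ext * st$n_gap))
}

# best local score: the optimum over every pair of substrings (plus the
# empty alignment at 0)
oracle_local <- function(a, b, match, mismatch, gap, open, ext) {
  best <- c(linear = 0, affine = 0)
  for (i1 in seq_along(a)) for (i2 in i1:length(a))
    for (j1 in seq_along(b)) for (j2 in j1:length(b)) {
      g <- oracle_global(a[i1:i2], b[j1:j2], match, mismatch, gap, open, ext)
      best <- pmax(best, g)
    }
  best
}

# longest common subsequence by enumerating all subsequences of the
# shorter sequence and greedily testing containment in the longer
oracle_lcs <- function(a, b) {
  if (length(a) > length(b)) { tmp <- a; a <- b; b <- tmp }
  if (length(a) == 0L) return(0L)
  best <- 0L
  for (mask in 0:(2^length(a) - 1L)) {
    sub <- a[bitwAnd(mask, bitwShiftL(1L, seq_along(a) - 1L)) > 0L]
    if (length(sub) <= best) next
    j <- 1L; ok <- TRUE
    for (x in sub) {
      if (j > length(b)) { ok <- FALSE; break }
      w <- which(b[j:length(b)] == x)
      if (!length(w)) { ok <- FALSE; break }
      j <- j + w[1L]
    }
    if (ok) best <- length(sub)
  }
  best
}

random_seq_pair <- function(max_len = 6, alphabet = c("A", "C", "G", "T")) {
  list(a = sample(alphabet, sample.int(max_len, 1L), replace = TRUE),
       b = sample(alphabet, sample.int(max_len, 1L), replace = TRUE))
}
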