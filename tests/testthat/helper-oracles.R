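# Independent oracles and small fixture builders shared by the tests.
# Each oracle re-derives the quantity from first principles (enumeration or
# the textbook closed form) and never calls the implementation under test.

DNA4 <- c("A", "C", "G", "T")
COMP4 <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

rand_dna_str <- function(n, prob = NULL) {
  paste(sample(DNA4, n, replace = TRUE, prob = prob), collapse = "")
}

revcomp_str <- function(x) {
  paste(rev(COMP4[strsplit(x, "")[[1]]]), collapse = "")
}

# ---- brute-force SSR enumerator -------------------------------------------
oracle_ssrs <- function(seq, min_reps = c(10, 6, 5, 5, 5, 5)) {
  v <- strsplit(seq, "")[[1]]; n <- length(v)
  hits <- list()
  primitive <- function(m) {
    u <- length(m)
    for (dd in seq_len(u - 1)) {
      if (u %% dd == 0 && all(m == m[((seq_len(u) - 1) %% dd) + 1])) return(FALSE)
    }
    TRUE
  }
  for (u in 1:6) {
    i <- 1
    while (i + u - 1 <= n) {
      motif <- v[i:(i + u - 1)]
      if (i > 1 && v[i - 1] == v[i - 1 + u] && v[i - 1] %in% DNA4) {
        i <- i + 1; next
      }
      L <- u
      while (i + L <= n && v[i + L] == v[i + L - u] && v[i + L] %in% DNA4) L <- L + 1
      cnt <- L %/% u
      if (cnt >= min_reps[u] && all(motif %in% DNA4) && primitive(motif)) {
        hits[[length(hits) + 1]] <- data.frame(
          start = i, end = i + u * cnt - 1,
          motif = paste(motif, collapse = ""), unit = u, n_repeats = cnt)
      }
      i <- i + max(1, L - u + 1)
    }
  }
  if (!length(hits)) {
    return(data.frame(start = integer(), end = integer(), motif = character(),
                      unit = integer(), n_repeats = integer()))
  }
  H <- do.call(rbind, hits)
  keep <- rep(TRUE, nrow(H))
  for (a in order(-H$unit)) {
    if (!keep[a]) next
    ov <- H$start <= H$end[a] & H$end >= H$start[a] & H$unit < H$unit[a]
    keep[ov] <- FALSE
  }
  H <- H[keep, , drop = FALSE]
  H <- H[order(H$start), ]
  rownames(H) <- NULL
  for (cc in names(H)) if (is.numeric(H[[cc]])) H[[cc]] <- as.integer(H[[cc]])
  H
}

# ---- brute-force dispersed-repeat enumerator ------------------------------
# per-diagonal enumeration of all match-ended windows with <= h mismatches,
# keeping only windows not contained in another valid window
oracle_dispersed <- function(seq, min_len, h) {
  v <- strsplit(seq, "")[[1]]; n <- length(v)
  rc <- rev(COMP4[v])
  hits <- list()
  scan <- function(other, orient) {
    for (d in (-(n - 1)):(n - 1)) {
      if (orient == "forward" && d <= 0) next
      lo <- max(1, 1 - d); hi <- min(n, n - d)
      if (hi - lo + 1 < min_len) next
      idx <- lo:hi
      cmp <- v[idx] == other[idx + d] & v[idx] %in% DNA4
      m <- which(cmp); if (length(m) < 2) next
      cs <- cumsum(!cmp)
      mmM <- outer(cs[m], cs[m] - (!cmp)[m], FUN = function(b, a) b - a)
      lenM <- outer(m, m, FUN = function(b, a) b - a + 1)
      ok <- which(t(mmM) >= 0 & t(lenM) >= min_len & t(mmM) <= h, arr.ind = TRUE)
      # rows of ok: (a index, b index) with a <= b implied by len >= min_len
      if (nrow(ok) == 0) next
      W <- cbind(m[ok[, 1]], m[ok[, 2]],
                 mmM[cbind(ok[, 2], ok[, 1])])
      keep <- vapply(seq_len(nrow(W)), function(i) {
        !any(W[, 1] <= W[i, 1] & W[i, 2] <= W[, 2] &
               (W[, 1] < W[i, 1] | W[i, 2] < W[, 2]))
      }, TRUE)
      W <- W[keep, , drop = FALSE]
      for (r in seq_len(nrow(W))) {
        a <- W[r, 1] + lo - 1; b <- W[r, 2] + lo - 1; len <- b - a + 1
        if (orient == "forward") { p1 <- a; p2 <- a + d }
        else { p1 <- a; p2 <- n - (b + d) + 1 }
        if (p2 < p1) { tmp <- p1; p1 <- p2; p2 <- tmp }
        if (p2 < p1 + len) next
        hits[[length(hits) + 1]] <<- data.frame(
          kind = orient, start1 = p1, end1 = p1 + len - 1,
          start2 = p2, end2 = p2 + len - 1, length = len, mismatches = W[r, 3])
      }
    }
  }
  scan(v, "forward"); scan(rc, "palindromic")
  if (!length(hits)) {
    return(data.frame(kind = character(), start1 = integer(), end1 = integer(),
                      start2 = integer(), end2 = integer(), length = integer(),
                      mismatches = integer()))
  }
  out <- unique(do.call(rbind, hits))
  out <- out[order(out$kind, out$start1, out$start2, out$length), ]
  rownames(out) <- NULL
  for (cc in names(out)) if (is.numeric(out[[cc]])) out[[cc]] <- as.integer(out[[cc]])
  out
}

normalize_hits <- function(df) {
  df <- as.data.frame(df)
  df <- df[order(df$kind, df$start1, df$start2, df$length), ]
  rownames(df) <- NULL
  for (cc in names(df)) if (is.numeric(df[[cc]])) df[[cc]] <- as.integer(df[[cc]])
  df
}

# ---- full-DP global affine alignment score (Gotoh, score only) ------------
oracle_nw_score <- function(a, b, match = 1, mismatch = -1,
                            open = 10, ext = 2) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  la <- length(A); lb <- length(B)
  NEG <- -1e18
  M <- matrix(NEG, la + 1, lb + 1); X <- M; Y <- M
  M[1, 1] <- 0
  for (i in seq_len(la)) X[i + 1, 1] <- -open - ext * i
  for (j in seq_len(lb)) Y[1, j + 1] <- -open - ext * j
  for (i in seq_len(la)) {
    for (j in seq_len(lb)) {
      s <- if (A[i] == B[j]) match else mismatch
      M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + s
      X[i + 1, j + 1] <- max(M[i, j + 1] - open - ext, Y[i, j + 1] - open - ext,
                             X[i, j + 1] - ext)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - open - ext, X[i + 1, j] - open - ext,
                             Y[i + 1, j] - ext)
    }
  }
  max(M[la + 1, lb + 1], X[la + 1, lb + 1], Y[la + 1, lb + 1])
}

# ---- forward K80 site simulation ------------------------------------------
# transition probabilities derived from the standard K80 matrix with
# expected distance d = (alpha + 2 beta) t and kappa = alpha / beta
evolve_k80 <- function(seq, d, kappa = 2) {
  v <- strsplit(seq, "")[[1]]
  bt <- d / (kappa + 2); at <- kappa * bt
  p_ts <- 0.25 + 0.25 * exp(-4 * bt) - 0.5 * exp(-2 * (at + bt))
  p_tv <- 0.5 - 0.5 * exp(-4 * bt)
  ts <- c(A = "G", G = "A", C = "T", T = "C")
  tv1 <- c(A = "C", G = "C", C = "A", T = "A")
  tv2 <- c(A = "T", G = "T", C = "G", T = "G")
  u <- runif(length(v))
  out <- v
  i_ts <- u < p_ts
  i_tv <- !i_ts & u < p_ts + p_tv
  out[i_ts] <- ts[v[i_ts]]
  half <- runif(sum(i_tv)) < 0.5
  out[i_tv] <- ifelse(half, tv1[v[i_tv]], tv2[v[i_tv]])
  paste(out, collapse = "")
}

# ---- small study-shaped generator spec for fast tests ---------------------
small_spec <- function(seed, ...) {
  plastome_spec(lsc_len = 20000, ssc_len = 4000, ir_len = 6000,
                n_genes = c(LSC = 10L, SSC = 3L, IR = 4L), seed = seed, ...)
}

no_tandem <- function() {
  tibble::tibble(unit_len = integer(), n_copies = integer(),
                 mismatches = integer())
}

no_dispersed <- function() {
  tibble::tibble(kind = character(), length = integer(),
                 mismatches = integer())
}

no_ssr <- function() {
  tibble::tibble(motif = character(), n_repeats = integer())
}

# sparse repeat complement for very small genomes
tiny_spec <- function(seed, lsc_len = 6000, ssc_len = 1500, ir_len = 1500,
                      n_genes = c(LSC = 8L, SSC = 2L, IR = 2L)) {
  plastome_spec(lsc_len = lsc_len, ssc_len = ssc_len, ir_len = ir_len,
                n_genes = n_genes,
                planted_ssrs = tibble::tibble(motif = c("A", "AT"),
                                              n_repeats = c(10L, 6L)),
                planted_tandems = no_tandem(),
                planted_dispersed = no_dispersed(),
                seed = seed)
}
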