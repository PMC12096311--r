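# Independent oracles: a pure-R affine-gap global aligner (Gotoh with
# traceback), brute-force k-mer pair counting, exhaustive assignment and
# exhaustive call/truth matching.  These share no code with the package's
# alignment or matching paths.

# Global affine alignment; returns matches, columns (alignment length
# including gaps) and identity.
oracle_global_align <- function(a, b, match = 1, mismatch = -2,
                                gap_open = 4, gap_ext = 1) {
  va <- strsplit(a, "")[[1]]
  vb <- strsplit(b, "")[[1]]
  n <- length(va); m <- length(vb)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)   # gap in b (consume a)
  Y <- matrix(NEG, n + 1, m + 1)   # gap in a (consume b)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -gap_open - gap_ext * (i - 1)
  for (j in 2:(m + 1)) Y[1, j] <- -gap_open - gap_ext * (j - 1)
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (va[i - 1] == vb[j - 1]) match else mismatch
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] - gap_open - gap_ext,
                     X[i - 1, j] - gap_ext)
      Y[i, j] <- max(M[i, j - 1] - gap_open - gap_ext,
                     Y[i, j - 1] - gap_ext)
    }
  }
  # traceback
  i <- n + 1; j <- m + 1
  state <- which.max(c(M[i, j], X[i, j], Y[i, j]))
  matches <- 0L; cols <- 0L
  while (i > 1 || j > 1) {
    cols <- cols + 1L
    if (state == 1 && i > 1 && j > 1) {
      if (va[i - 1] == vb[j - 1]) matches <- matches + 1L
      s <- if (va[i - 1] == vb[j - 1]) match else mismatch
      prev <- c(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
      state <- which.max(prev)
      i <- i - 1; j <- j - 1
    } else if (state == 2 || j == 1) {
      up <- c(M[i - 1, j] - gap_open - gap_ext, X[i - 1, j] - gap_ext)
      state <- if (i > 2 && up[2] >= up[1]) 2L else 1L
      if (j == 1 && i > 1) state <- if (i > 2) 2L else 1L
      i <- i - 1
    } else {
      left <- c(M[i, j - 1] - gap_open - gap_ext, Y[i, j - 1] - gap_ext)
      state <- if (j > 2 && left[2] >= left[1]) 3L else 1L
      j <- j - 1
    }
  }
  list(matches = matches, columns = cols, identity = matches / cols)
}

# All (i, j) pairs with a[i..i+k-1] == b[j..j+k-1] (forward strand).
oracle_kmer_pairs <- function(a, b, k) {
  na <- nchar(a); nb <- nchar(b)
  if (na < k || nb < k) return(0L)
  ka <- substring(a, 1:(na - k + 1), k:na)
  kb <- substring(b, 1:(nb - k + 1), k:nb)
  sum(outer(ka, kb, "=="))
}

# Maximum total-weight one-to-one assignment by brute force.
oracle_assignment <- function(w) {
  nr <- nrow(w); nc <- ncol(w)
  best <- -Inf
  rec <- function(i, used, acc) {
    if (i > nr) { best <<- max(best, acc); return(invisible()) }
    rec(i + 1, used, acc)                 # row left unassigned
    for (j in seq_len(nc)) {
      if (!used[j]) { used[j] <- TRUE; rec(i + 1, used, acc + w[i, j])
        used[j] <- FALSE }
    }
  }
  rec(1, rep(FALSE, nc), 0)
  best
}

# Maximum TP count over all one-to-one assignments of eligible pairs.
oracle_match_tp <- function(calls, truth, params, sub_strict = FALSE) {
  ca <- svrefine:::.ev_table(calls)
  tr <- svrefine:::.ev_table(truth)
  ca <- ca[ca$size >= params$sizemin & ca$size <= params$sizemax, ,
           drop = FALSE]
  tr <- tr[tr$size >= params$sizemin & tr$size <= params$sizemax, ,
           drop = FALSE]
  nc <- nrow(ca); nt <- nrow(tr)
  elig <- matrix(FALSE, nc, nt)
  for (i in seq_len(nc)) {
    for (j in seq_len(nt)) {
      elig[i, j] <- svrefine:::.eligible(ca[i, ], tr[j, ], params,
                                         sub_strict)
    }
  }
  best <- 0L
  rec <- function(i, used, acc) {
    if (acc + (nc - i + 1) <= best) return(invisible())
    if (i > nc) { best <<- max(best, acc); return(invisible()) }
    rec(i + 1, used, acc)
    for (j in seq_len(nt)) {
      if (!used[j] && elig[i, j]) {
        used[j] <- TRUE; rec(i + 1, used, acc + 1L); used[j] <- FALSE
      }
    }
  }
  rec(1L, rep(FALSE, nt), 0L)
  best
}

# Every equivalent placement of a length-d deletion matching the one at
# `a`, by full string reconstruction (truly exhaustive).
oracle_del_placements <- function(x, a, d) {
  n <- nchar(x)
  target <- paste0(substr(x, 1, a - 1), substr(x, a + d, n))
  which(vapply(seq_len(n - d + 1), function(p) {
    paste0(substr(x, 1, p - 1), substr(x, p + d, n)) == target
  }, logical(1)))
}
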