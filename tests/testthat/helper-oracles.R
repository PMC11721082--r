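# Independent oracles used to cross-check package implementations.

# Brute-force GC counting by character comparison.
oracle_gc <- function(seqs) {
  chars <- unlist(strsplit(toupper(paste(seqs, collapse = "")), ""))
  n_gc <- sum(chars %in% c("G", "C"))
  n_acgt <- sum(chars %in% c("A", "C", "G", "T"))
  n_gc / n_acgt
}

# Explicit double-loop confusion matrix.
oracle_confusion <- function(truth, pred, classes) {
  cm <- matrix(0L, length(classes), length(classes),
               dimnames = list(classes, classes))
  for (i in seq_along(truth)) {
    for (a in classes) {
      for (b in classes) {
        if (truth[i] == a && pred[i] == b) cm[a, b] <- cm[a, b] + 1L
      }
    }
  }
  cm
}

# Smith-Waterman local alignment with affine gaps (Gotoh), BLOSUM62.
# Gap of length L costs gap_open + L * gap_ext, matching the aligner
# convention used by the package. Returns score, percent identity over
# the alignment (including gap columns) and alignment length.
oracle_sw <- function(a, b, gap_open = 10, gap_ext = 1) {
  data_env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = data_env)
  S <- get("BLOSUM62", envir = data_env)
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  M <- matrix(0, n + 1, m + 1)
  Ix <- matrix(NEG, n + 1, m + 1)  # gap in b (consumes a)
  Iy <- matrix(NEG, n + 1, m + 1)  # gap in a (consumes b)
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      sub <- S[A[i - 1], B[j - 1]]
      M[i, j] <- max(0, M[i - 1, j - 1] + sub, Ix[i - 1, j - 1] + sub,
                     Iy[i - 1, j - 1] + sub)
      Ix[i, j] <- max(M[i - 1, j] - gap_open - gap_ext,
                      Ix[i - 1, j] - gap_ext)
      Iy[i, j] <- max(M[i, j - 1] - gap_open - gap_ext,
                      Iy[i, j - 1] - gap_ext)
    }
  }
  best <- which(M == max(M), arr.ind = TRUE)[1, ]
  score <- max(M)
  # traceback from the best cell through whichever state explains the value
  i <- best[1]; j <- best[2]
  state <- "M"
  n_match <- 0L; n_col <- 0L
  while (i > 1 || j > 1) {
    if (state == "M") {
      if (M[i, j] == 0) break
      n_col <- n_col + 1L
      if (A[i - 1] == B[j - 1]) n_match <- n_match + 1L
      sub <- S[A[i - 1], B[j - 1]]
      prev <- M[i, j] - sub
      if (i > 1 && j > 1 && abs(M[i - 1, j - 1] - prev) < 1e-9) {
        state <- "M"
      } else if (abs(Ix[i - 1, j - 1] - prev) < 1e-9) {
        state <- "Ix"
      } else {
        state <- "Iy"
      }
      i <- i - 1; j <- j - 1
    } else if (state == "Ix") {
      n_col <- n_col + 1L
      if (abs(Ix[i, j] - (M[i - 1, j] - gap_open - gap_ext)) < 1e-9) {
        state <- "M"
      }
      i <- i - 1
    } else {
      n_col <- n_col + 1L
      if (abs(Iy[i, j] - (M[i, j - 1] - gap_open - gap_ext)) < 1e-9) {
        state <- "M"
      }
      j <- j - 1
    }
  }
  list(score = score, pid = 100 * n_match / n_col, length = n_col)
}

# One-way AAI of a query proteome against one reference proteome by
# exhaustive all-pairs alignment: best oracle hit per query protein.
oracle_aai <- function(query, ref_proteins, min_score = 60, af_floor = 20) {
  best_pid <- numeric(0)
  for (q in query) {
    scores <- vapply(ref_proteins, function(r) oracle_sw(q, r)$score, 0)
    if (max(scores) >= min_score) {
      best_pid <- c(best_pid, oracle_sw(q, ref_proteins[[which.max(scores)]])$pid)
    }
  }
  af <- 100 * length(best_pid) / length(query)
  aai <- if (length(best_pid) > 0) mean(best_pid) else 0
  list(af = af, aai = if (af < af_floor) 0 else aai, aai_raw = aai)
}
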