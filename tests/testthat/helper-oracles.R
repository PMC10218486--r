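# Independent oracles used across the suite. These deliberately take
# different implementation paths from the package code they check.

# Pure-R iterative dynamic program for the restricted (optimal string
# alignment) Damerau-Levenshtein distance. Checks the C++ kernel.
r_dl_dp <- function(a, b) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  m <- length(A)
  n <- length(B)
  d <- matrix(0L, m + 1L, n + 1L)
  d[, 1L] <- 0:m
  d[1L, ] <- 0:n
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      cost <- if (A[i] == B[j]) 0L else 1L
      best <- min(d[i, j + 1L] + 1L, d[i + 1L, j] + 1L, d[i, j] + cost)
      if (i > 1L && j > 1L && A[i] == B[j - 1L] && A[i - 1L] == B[j]) {
        best <- min(best, d[i - 1L, j - 1L] + 1L)
      }
      d[i + 1L, j + 1L] <- best
    }
  }
  d[m + 1L, n + 1L]
}

# Brute-force enumeration of the edit recurrence, no memoization: every
# branch of the recursion tree is explored. Only usable on short strings;
# anchors r_dl_dp itself.
dl_naive <- function(a, b) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  rec <- function(i, j) {
    if (i == 0L) return(j)
    if (j == 0L) return(i)
    cost <- if (A[i] == B[j]) 0L else 1L
    best <- min(rec(i - 1L, j) + 1L, rec(i, j - 1L) + 1L,
                rec(i - 1L, j - 1L) + cost)
    if (i > 1L && j > 1L && A[i] == B[j - 1L] && A[i - 1L] == B[j]) {
      best <- min(best, rec(i - 2L, j - 2L) + 1L)
    }
    best
  }
  rec(length(A), length(B))
}

# All pose-letter strings of length 0..maxlen (length 0 = "").
all_pose_strings <- function(maxlen) {
  out <- ""
  frontier <- ""
  for (k in seq_len(maxlen)) {
    frontier <- as.vector(outer(frontier, c("C", "S", "P"), paste0))
    out <- c(out, frontier)
  }
  out
}

# Transitive closure of a (child, parent) edge table by boolean matrix
# powering (Warshall-style fixpoint), independent of the package's
# per-node BFS.
closure_oracle <- function(edges) {
  nodes <- sort(unique(c(edges$child, edges$parent)), method = "radix")
  A <- matrix(FALSE, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  A[cbind(edges$child, edges$parent)] <- TRUE
  R <- A
  repeat {
    R2 <- R | ((R %*% A) > 0)
    if (identical(R2, R)) break
    R <- R2
  }
  idx <- which(R, arr.ind = TRUE)
  out <- data.frame(child = nodes[idx[, 1]], ancestor = nodes[idx[, 2]],
                    stringsAsFactors = FALSE)
  out <- out[order(out$child, out$ancestor, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Pose letters of a stream as one window string.
stream_letters_chr <- function(s) paste(s$events$pose, collapse = "")

# Tiny taxonomy used in several tests.
toy_taxonomy <- function() {
  data.frame(
    class = c("Patron", "Patron", "State of mind", "State of mind"),
    subclass = c("Walking", "Sitting", "Nervous", "Depressed"),
    stringsAsFactors = FALSE)
}
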