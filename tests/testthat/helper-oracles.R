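# Independent oracles used across the suite. None of these share code with
# the package's aligner or simulator.

# Optimal overlap-alignment score by direct recursion over the alignment
# definition (free end gaps on both sequences: start on the first row or
# column, end on the last row or column). Memoised per (i, j) suffix, but
# written independently of the package's matrix-filling C++ code.
oracle_align_score <- function(read, ref, match = 2L, mismatch = -1L,
                               gap = -1L) {
  a <- strsplit(read, "")[[1]]
  b <- strsplit(ref, "")[[1]]
  n <- length(a)
  m <- length(b)
  sub <- function(x, y) {
    if (x == "N" || y == "N") return(mismatch)
    if (x == y) match else mismatch
  }
  memo <- new.env(parent = emptyenv())
  # best score aligning read[i..n] vs ref[j..m] where the alignment must
  # run until one sequence is exhausted (the other's tail is then free)
  core <- function(i, j) {
    if (i > n || j > m) return(0L)
    key <- paste(i, j)
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    v <- max(sub(a[i], b[j]) + core(i + 1L, j + 1L),
             gap + core(i + 1L, j),
             gap + core(i, j + 1L))
    memo[[key]] <- v
    v
  }
  # free leading trim of one sequence's prefix
  best <- -Inf
  for (i in 1:(n + 1L)) best <- max(best, core(i, 1L))
  for (j in 1:(m + 1L)) best <- max(best, core(1L, j))
  best
}

# plain-string editors for the normalization oracle
str_insert <- function(s, pos, bases)  # insertion before 0-based pos
  paste0(substr(s, 1, pos), bases, substr(s, pos + 1, nchar(s)))
str_delete <- function(s, pos, len)    # delete [pos, pos+len)
  paste0(substr(s, 1, pos), substr(s, pos + len + 1, nchar(s)))

# leftmost equivalent placement of an indel by scanning every position and
# comparing the edited strings
oracle_canonical_insertion <- function(ref, pos, bases) {
  target <- str_insert(ref, pos, bases)
  L <- nchar(ref)
  k <- nchar(bases)
  for (q in 0:L) {
    # any rotation of the inserted bases may reproduce the read
    b <- bases
    for (r in seq_len(k)) {
      if (str_insert(ref, q, b) == target) return(list(pos = q, bases = b))
      b <- paste0(substr(b, k, k), substr(b, 1, k - 1))
    }
  }
  stop("unreachable")
}

oracle_canonical_deletion <- function(ref, pos, len) {
  target <- str_delete(ref, pos, len)
  for (q in 0:(nchar(ref) - len)) {
    if (str_delete(ref, q, len) == target) return(q)
  }
  stop("unreachable")
}

# run length at every position by direct scan
oracle_run_lengths <- function(seq) {
  s <- strsplit(seq, "")[[1]]
  vapply(seq_along(s), function(i) {
    j0 <- i
    while (j0 > 1 && s[j0 - 1] == s[i]) j0 <- j0 - 1
    j1 <- i
    while (j1 < length(s) && s[j1 + 1] == s[i]) j1 <- j1 + 1
    as.integer(j1 - j0 + 1)
  }, integer(1))
}

# rule-table classification oracle over an event multiset, written straight
# from the category definitions
oracle_classify <- function(types, lengths) {
  if (length(types) == 0) return("accurate")
  if (all(types == "insertion")) {
    if (sum(lengths) == 1) return("single_insertion")
    return("multi_insertion")
  }
  if (length(types) == 1 && lengths == 1) {
    if (types == "deletion") return("single_deletion")
    if (types == "substitution") return("single_substitution")
  }
  "mixed"
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# small shared fixture
tiny_ref <- function(seed = 11) generate_reference(seed = seed)

ins_event <- function(pos, bases) data.frame(
  event_type = "insertion", ref_pos = as.integer(pos),
  ref_interval_end = as.integer(pos), length = nchar(bases),
  bases = bases, ref_bases = "")

del_event <- function(ref, pos, len = 1L) data.frame(
  event_type = "deletion", ref_pos = as.integer(pos),
  ref_interval_end = as.integer(pos + len), length = as.integer(len),
  bases = "", ref_bases = substr(ref, pos + 1, pos + len))

sub_event <- function(ref, pos, base) data.frame(
  event_type = "substitution", ref_pos = as.integer(pos),
  ref_interval_end = as.integer(pos + 1), length = 1L,
  bases = base, ref_bases = substr(ref, pos + 1, pos + 1))
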