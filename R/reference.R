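#' Construct an annotated antibody variable-domain reference
#'
#' Bundles a Sanger-verified (or simulated) nucleotide sequence of an antibody
#' FV domain with its region annotation, reading frame, and the conserved
#' residues (the framework cysteines and the FR2 tryptophan) used when
#' calling functionality.
#'
#' All coordinates are 0-based; region intervals are half-open
#' \code{[start, end)} in nucleotides and must tile a contiguous span without
#' overlap. Codon indices for conserved positions count from
#' \code{frame_offset}.
#'
#' @param id Sequence identifier.
#' @param seq Nucleotide string over A/C/G/T.
#' @param regions Data frame with columns \code{region}, \code{start},
#'   \code{end}: half-open nucleotide intervals for FR1, CDR1, FR2, CDR2,
#'   FR3, CDR3 in order.
#' @param frame_offset Integer 0-2; translation starts at this nucleotide.
#' @param conserved_positions Data frame with columns \code{codon} (0-based
#'   codon index relative to \code{frame_offset}) and \code{aa} (expected
#'   amino acid, "C" or "W"), or NULL.
#' @return An object of class \code{ab_reference}.
#' @seealso [generate_reference()] to simulate one.
#' @export
ab_reference <- function(id, seq, regions, frame_offset = 0L,
                         conserved_positions = NULL) {
  seq <- toupper(seq)
  ref <- structure(
    list(
      id = as.character(id),
      seq = seq,
      length = nchar(seq),
      frame_offset = as.integer(frame_offset),
      regions = regions,
      conserved_positions = conserved_positions
    ),
    class = "ab_reference"
  )
  validate_reference(ref)
  ref
}

#' Validate an ab_reference against its invariants
#'
#' Checks alphabet, contiguous non-overlapping region tiling, absence of
#' in-frame stop codons, and that every conserved codon translates to its
#' expected residue. Called by the constructor; exported because tests and
#' user-supplied references use it directly.
#'
#' @param ref An \code{ab_reference}.
#' @return \code{ref}, invisibly; errors describe the first violated
#'   invariant.
#' @export
validate_reference <- function(ref) {
  stopifnot(inherits(ref, "ab_reference"))
  if (grepl("[^ACGT]", ref$seq))
    stop("reference sequence contains characters outside {A,C,G,T}")
  rg <- ref$regions
  need <- c("FR1", "CDR1", "FR2", "CDR2", "FR3", "CDR3")
  if (!identical(rg$region, need))
    stop("regions must be exactly FR1, CDR1, FR2, CDR2, FR3, CDR3 in order")
  if (any(rg$end <= rg$start))
    stop("zero-length or inverted region interval")
  if (any(rg$start[-1] != rg$end[-nrow(rg)]))
    stop("regions must tile a contiguous span without gaps or overlap")
  if (rg$end[nrow(rg)] > ref$length)
    stop("region annotation extends beyond the sequence")
  aa <- translate_dna(substr(ref$seq, ref$frame_offset + 1L, ref$length))
  if (grepl("*", aa, fixed = TRUE))
    stop("reference contains an in-frame stop codon")
  cp <- ref$conserved_positions
  if (!is.null(cp) && nrow(cp)) {
    got <- vapply(cp$codon, function(ci)
      substr(aa, ci + 1L, ci + 1L), character(1))
    if (!all(got == cp$aa))
      stop("conserved codon(s) do not translate to the expected residue")
  }
  invisible(ref)
}

#' @export
print.ab_reference <- function(x, ...) {
  cat(sprintf("ab_reference '%s': %d nt, frame offset %d\n",
              x$id, x$length, x$frame_offset))
  cat("  regions: ",
      paste(sprintf("%s[%d,%d)", x$regions$region, x$regions$start,
                    x$regions$end), collapse = " "), "\n", sep = "")
  if (!is.null(x$conserved_positions))
    cat("  conserved codons: ",
        paste(sprintf("%s@%d", x$conserved_positions$aa,
                      x$conserved_positions$codon), collapse = " "),
        "\n", sep = "")
  invisible(x)
}

#' Default FV-domain region layout
#'
#' Region lengths (nt) of a typical heavy-chain variable domain; all
#' multiples of 3 so region boundaries fall on codon boundaries.
#'
#' @return Named integer vector FR1..CDR3.
#' @export
default_layout <- function() {
  c(FR1 = 78L, CDR1 = 24L, FR2 = 51L, CDR2 = 30L, FR3 = 114L, CDR3 = 33L)
}

#' Generate a random antibody-like reference sequence
#'
#' Simulates an annotated FV-domain reference: a stop-free random coding
#' sequence with the requested region layout, conserved framework residues
#' (Cys at the ends of FR1 and FR3, Trp opening FR2), and planted polyG
#' runs, one of which always falls inside CDR1 — the kind of short
#' homopolymer stretch where pyrosequencing indel errors concentrate.
#'
#' @param layout Named vector of region lengths in nt (names FR1..CDR3, each
#'   a multiple of 3, total >= 150). See [default_layout()].
#' @param gc_bias Probability mass on G+C when drawing bases (default 0.5).
#' @param polyg_hotspots Number of codon-aligned GGG runs to plant (>= 1;
#'   the first is placed inside CDR1).
#' @param seed Integer seed; the same seed reproduces the same reference.
#' @param id Identifier for the generated reference.
#' @return An \code{ab_reference}.
#' @examples
#' ref <- generate_reference(seed = 1)
#' ref
#' @export
generate_reference <- function(layout = default_layout(), gc_bias = 0.5,
                               polyg_hotspots = 2L, seed = 1L, id = "ref1") {
  need <- c("FR1", "CDR1", "FR2", "CDR2", "FR3", "CDR3")
  if (!all(need %in% names(layout)))
    stop("layout must name all of FR1, CDR1, FR2, CDR2, FR3, CDR3")
  layout <- as.integer(layout[need])
  names(layout) <- need
  if (any(layout <= 0L)) stop("zero-length region in layout")
  if (any(layout %% 3L != 0L))
    stop("region lengths must be multiples of 3")
  total <- sum(layout)
  if (total < 150L) stop("total reference length must be >= 150 nt")
  if (polyg_hotspots < 1L) stop("polyg_hotspots must be >= 1")

  ends <- cumsum(layout)
  regions <- data.frame(
    region = need,
    start = c(0L, ends[-6L]),
    end = ends,
    row.names = NULL
  )

  ncod <- total %/% 3L
  pb <- c(A = (1 - gc_bias) / 2, C = gc_bias / 2,
          G = gc_bias / 2, T = (1 - gc_bias) / 2)

  local_seed(seed, {
    codons <- character(ncod)
    for (k in seq_len(ncod)) {
      repeat {
        cd <- collapse(sample(BASES, 3L, replace = TRUE, prob = pb))
        if (!(cd %in% STOP_CODONS)) break
      }
      codons[k] <- cd
    }

    # conserved residues: Cys closing FR1 and FR3, Trp opening FR2
    cys1 <- regions$end[1] %/% 3L - 1L
    trp <- regions$start[3] %/% 3L
    cys2 <- regions$end[5] %/% 3L - 1L
    codons[cys1 + 1L] <- "TGC"
    codons[trp + 1L] <- "TGG"
    codons[cys2 + 1L] <- "TGC"
    conserved <- data.frame(codon = c(cys1, trp, cys2), aa = c("C", "W", "C"))

    # plant codon-aligned GGG runs; avoid conserved codons and G neighbours
    # so every planted run stays a maximal run of length 3
    plant_in <- function(cod_lo, cod_hi, taken) {
      cand <- setdiff(seq(cod_lo, cod_hi), taken)
      for (ci in sample(cand)) {
        left_ok <- ci == 0L || substr(codons[ci], 3L, 3L) != "G"
        right_ok <- ci == ncod - 1L || substr(codons[ci + 2L], 1L, 1L) != "G"
        if (left_ok && right_ok) return(ci)
      }
      stop("could not place a polyG hotspot; try another seed")
    }
    taken <- conserved$codon
    hot <- integer(0)
    cdr1_cod <- c(regions$start[2] %/% 3L, regions$end[2] %/% 3L - 1L)
    ci <- plant_in(cdr1_cod[1], cdr1_cod[2], taken)
    codons[ci + 1L] <- "GGG"
    taken <- c(taken, ci - 1L, ci, ci + 1L)
    hot <- ci
    while (length(hot) < polyg_hotspots) {
      ci <- plant_in(1L, ncod - 2L, taken)
      codons[ci + 1L] <- "GGG"
      taken <- c(taken, ci - 1L, ci, ci + 1L)
      hot <- c(hot, ci)
    }

    ab_reference(id, collapse(codons), regions,
                 frame_offset = 0L, conserved_positions = conserved)
  })
}

#' Maximal homopolymer runs of a sequence
#'
#' Run-length encodes a nucleotide string. Used to place simulated indels
#' and to attach homopolymer context to observed events.
#'
#' @param seq Nucleotide string.
#' @return Data frame with columns \code{base}, \code{start} (0-based),
#'   \code{len}; one row per maximal run (including runs of length 1).
#' @export
homopolymer_runs <- function(seq) {
  r <- rle(chars(seq))
  len <- r$lengths
  data.frame(
    base = r$values,
    start = cumsum(c(0L, len[-length(len)])),
    len = as.integer(len),
    row.names = NULL
  )
}
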