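# Reference amplicon: the 225-bp target carrying the candidate editing
# positions. Candidate sites are named A..N and must sit on an 'A' in the
# reference (A-to-I editing is read out as A->G by the sequencer).

#' Construct a reference amplicon
#'
#' Bundles a target sequence with its ordered map of candidate A-to-I
#' editing positions. Offsets are 0-based internally; exported tables use
#' 1-based positions and say so in their headers.
#'
#' @param name Amplicon name.
#' @param sequence Nucleotide string (A/C/G/T).
#' @param sites data.frame with columns `label` (single letters, unique)
#'   and `offset` (0-based, strictly increasing, each on an 'A').
#' @return An object of class `reference_amplicon`.
#' @export
reference_amplicon <- function(name, sequence, sites) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (grepl("[^ACGT]", sequence)) {
    stop("reference sequence may only contain A/C/G/T")
  }
  sites <- as.data.frame(sites)
  stopifnot(all(c("label", "offset") %in% names(sites)))
  sites$label <- as.character(sites$label)
  sites$offset <- as.integer(sites$offset)
  if (anyDuplicated(sites$label)) stop("duplicate site labels")
  if (is.unsorted(sites$offset, strictly = TRUE)) {
    stop("candidate offsets must be unique and strictly increasing")
  }
  if (any(sites$offset < 0L) || any(sites$offset >= nchar(sequence))) {
    stop("candidate offset outside sequence bounds")
  }
  ref_bases <- substring(sequence, sites$offset + 1L, sites$offset + 1L)
  if (any(ref_bases != "A")) {
    bad <- sites$label[ref_bases != "A"]
    stop("reference base at candidate site(s) ", paste(bad, collapse = ", "),
         " is not 'A'")
  }
  structure(
    list(name = name, sequence = sequence, sites = sites),
    class = "reference_amplicon"
  )
}

# Fixed default target: 225 bp with 14 candidate A positions labelled A..N.
# The sequence is a synthetic stand-in for the genomic target (the analysis
# depends only on length and on the candidate positions being 'A').
.DEFAULT_AMPLICON_SEQ <- paste0(
  "CTAGCATAAGCAAGTGTCTGGATGAGTCTACAGCGTATAGCTCTATGATACTATCCAATT",
  "GTATTGGCAGGAGGTTGTCGACCCCATTATCATTAACCAAACCTAGAAATCGGTAATTAA",
  "TTGCCAGCTTTCTAGATAGCCTCACAGACCGAATGTTAGTGAGAGTTTAAGCTAGTTTTA",
  "ACTTAATGTTGATATATGGACATAGTGAGAGACCAAATGCAAACG"
)

.DEFAULT_SITE_POS_1BASED <- c(
  A = 12L, B = 30L, C = 45L, D = 58L, E = 72L, F = 89L, G = 105L,
  H = 120L, I = 138L, J = 152L, K = 170L, L = 185L, M = 200L, N = 215L
)

#' Default PDE8A intron-9 editing-island amplicon
#'
#' A synthetic 225-bp amplicon with 14 candidate editing positions labelled
#' A through N, mirroring the site naming used for the PDE8A editing
#' island. Site B is the dominant edited site under the default simulation
#' settings; sites C-F carry minor editing; A and G-N stay at background.
#'
#' @return A `reference_amplicon`.
#' @export
default_amplicon <- function() {
  reference_amplicon(
    name = "PDE8A_intron9_island",
    sequence = .DEFAULT_AMPLICON_SEQ,
    sites = data.frame(
      label = names(.DEFAULT_SITE_POS_1BASED),
      offset = unname(.DEFAULT_SITE_POS_1BASED) - 1L,
      stringsAsFactors = FALSE
    )
  )
}

#' @export
print.reference_amplicon <- function(x, ...) {
  cat("Reference amplicon:", x$name, "\n")
  cat("  length:", nchar(x$sequence), "bp;",
      nrow(x$sites), "candidate A sites:",
      paste(x$sites$label, collapse = ""), "\n")
  invisible(x)
}

#' Export the site map as a 1-based table
#'
#' @param ref A `reference_amplicon`.
#' @return data.frame with `label`, `position` (1-based) and `ref_base`.
#' @export
site_map_table <- function(ref) {
  data.frame(
    label = ref$sites$label,
    position = ref$sites$offset + 1L,
    ref_base = substring(ref$sequence, ref$sites$offset + 1L,
                         ref$sites$offset + 1L),
    stringsAsFactors = FALSE
  )
}
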