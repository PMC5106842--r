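# Amino-acid alphabet, residue-name tables and background composition.

#' The 20-letter amino-acid alphabet used throughout the package
#'
#' One-letter codes in alphabetical order. PSSM rows, background vectors and
#' sequence encodings all follow this order.
#'
#' @return Character vector of length 20.
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

# three-letter -> one-letter, standard residues
.aa3to1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)

# small fixed table of common modified residues; anything else becomes 'X'
.aa3to1_modified <- c(
  MSE = "M", # selenomethionine
  SEP = "S", # phosphoserine
  TPO = "T", # phosphothreonine
  PTR = "Y", # phosphotyrosine
  CSO = "C", # S-hydroxycysteine
  HYP = "P"  # hydroxyproline
)

.water_resnames <- c("HOH", "WAT", "DOD", "H2O")

#' Map three-letter residue names to one-letter codes
#'
#' Standard residues map to their usual one-letter code; a small fixed table
#' of common modified residues (MSE, SEP, TPO, PTR, CSO, HYP) maps to the
#' parent residue when `map_modified = TRUE`; everything else becomes `"X"`.
#'
#' @param aa3 Character vector of three-letter residue names.
#' @param map_modified Map common modified residues to their parent letter?
#' @return Character vector of one-letter codes.
#' @export
aa3_to_aa1 <- function(aa3, map_modified = TRUE) {
  aa3 <- toupper(aa3)
  out <- unname(.aa3to1[aa3])
  if (map_modified) {
    mod <- is.na(out) & aa3 %in% names(.aa3to1_modified)
    out[mod] <- unname(.aa3to1_modified[aa3[mod]])
  }
  out[is.na(out)] <- "X"
  out
}

#' Background amino-acid composition
#'
#' Robinson–Robinson amino-acid frequencies, a fixed general-protein
#' composition used as the default background for PSSM construction and for
#' the exact score distribution. The vector is normalised to sum to one and
#' named by [aa_alphabet()].
#'
#' @return Named numeric vector of length 20 summing to 1.
#' @export
dasp_background <- function() {
  f <- c(
    A = 0.07805, C = 0.01925, D = 0.05364, E = 0.06295, F = 0.03856,
    G = 0.07377, H = 0.02199, I = 0.05142, K = 0.05744, L = 0.09019,
    M = 0.02243, N = 0.04487, P = 0.05203, Q = 0.04264, R = 0.05129,
    S = 0.07120, T = 0.05841, V = 0.06441, W = 0.01330, Y = 0.03216
  )
  f / sum(f)
}

# BLOSUM62 from Biostrings, subset to the 20-letter alphabet (+ X)
.blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

# sum of BLOSUM62 scores over two equal-length residue strings; unknown
# letters (not in the matrix) score 0
blosum_string_score <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  if (nchar(a) == 0L) return(0)
  m <- .blosum62()
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  ok <- av %in% rownames(m) & bv %in% colnames(m)
  if (!any(ok)) return(0)
  sum(m[cbind(av[ok], bv[ok])])
}

# run a block of code under a fixed seed, restoring the caller's RNG state
with_fixed_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}
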