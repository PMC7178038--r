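# Physical constants and small shared helpers.

# Gas constant in kcal mol^-1 K^-1; energies are reported in kcal/mol
# throughout, temperatures are kelvin internally and degrees Celsius at
# user-facing DSC interfaces.
R_KCAL <- 1.987e-3

# One-letter codes of the 20 standard amino acids.
AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
         "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

AA3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
         E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
         M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
         Y = "TYR", V = "VAL")

celsius_to_kelvin <- function(x) x + 273.15
kelvin_to_celsius <- function(x) x - 273.15

#' Convert a temperature and free energy to an equilibrium constant and back
#' @noRd
dg_to_K <- function(dG, temperature) exp(-dG / (R_KCAL * temperature))

#' Split an amino-acid string into one-letter residues, with validation
#' @noRd
split_sequence <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence))
    stop("`sequence` must be a single character string", call. = FALSE)
  res <- strsplit(toupper(gsub("[[:space:]]", "", sequence)), "")[[1]]
  bad <- setdiff(unique(res), AA1)
  if (length(bad))
    stop("invalid residue code(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  res
}

# Evaluate a straight line given as c(intercept, slope).
line_at <- function(line, x) {
  if (!is.numeric(line) || length(line) != 2L)
    stop("baseline must be numeric c(intercept, slope)", call. = FALSE)
  line[[1L]] + line[[2L]] * x
}

# Run an expression under a temporary RNG seed, restoring global RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
      stop("`seed` must be a single integer", call. = FALSE)
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}
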