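# Sequence-level properties: charge census and isoelectric point.

# Bjellqvist pKa values as used by the ProtParam tool. The N-terminal pKa
# depends on the first residue.
PKA_NEG <- c(Cterm = 3.55, D = 4.05, E = 4.45, C = 9.00, Y = 10.00)
PKA_POS <- c(H = 5.98, K = 10.00, R = 12.00)
PKA_NTERM <- c(A = 7.59, M = 7.00, S = 6.93, P = 8.36, T = 6.82, V = 7.44,
               E = 7.70, G = 7.50)
PKA_NTERM_DEFAULT <- 7.50

#' Net protein charge at a given pH
#'
#' Henderson-Hasselbalch sum over titrating groups with the
#' Bjellqvist/ProtParam pKa set.
#'
#' @param pH pH value(s).
#' @param sequence amino-acid string.
#' @return Net charge (elementary charges), vectorized over `pH`.
#' @export
net_charge <- function(pH, sequence) {
  res <- split_sequence(sequence)
  counts <- table(factor(res, levels = AA1))
  nt_pka <- if (res[1L] %in% names(PKA_NTERM)) PKA_NTERM[[res[1L]]]
  else PKA_NTERM_DEFAULT
  pos <- function(pka, n) n / (1 + 10^(pH - pka))
  neg <- function(pka, n) n / (1 + 10^(pka - pH))
  z <- pos(nt_pka, 1)
  for (aa in names(PKA_POS)) z <- z + pos(PKA_POS[[aa]], counts[[aa]])
  z <- z - neg(PKA_NEG[["Cterm"]], 1)
  for (aa in c("D", "E", "C", "Y")) z <- z - neg(PKA_NEG[[aa]], counts[[aa]])
  z
}

#' Isoelectric point by bisection
#'
#' Root of [net_charge()] on pH 0-14, to `tol` pH units.
#'
#' @param sequence amino-acid string.
#' @param tol bisection tolerance (default 1e-4 pH units).
#' @return The pI.
#' @export
isoelectric_point <- function(sequence, tol = 1e-4) {
  lo <- 0; hi <- 14
  if (net_charge(lo, sequence) < 0 || net_charge(hi, sequence) > 0)
    stop("net charge does not change sign on pH 0-14", call. = FALSE)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (net_charge(mid, sequence) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Charged-residue census and isoelectric point
#'
#' Counts Glu, Asp, Arg, Lys and His; the acidic total is Glu + Asp and the
#' basic total Arg + Lys (His is reported in `notes` only, following the
#' convention of comparative ACP charge tables). The pI comes from
#' [isoelectric_point()].
#'
#' @param sequence amino-acid string.
#' @return An object of class `charge_census`: counts, totals, `pI`, `notes`.
#' @export
charge_census <- function(sequence) {
  res <- split_sequence(sequence)
  counts <- table(factor(res, levels = AA1))
  out <- list(Glu = counts[["E"]], Asp = counts[["D"]], Arg = counts[["R"]],
              Lys = counts[["K"]], His = counts[["H"]],
              acidic = counts[["E"]] + counts[["D"]],
              basic = counts[["R"]] + counts[["K"]],
              pI = isoelectric_point(sequence),
              notes = sprintf("His (%d) excluded from the basic total",
                              counts[["H"]]))
  class(out) <- "charge_census"
  out
}

#' @export
print.charge_census <- function(x, ...) {
  cat(sprintf("Acidic (Glu/Asp): %d (%d/%d)\nBasic (Arg/Lys): %d (%d/%d)\npI: %.2f\n%s\n",
              x$acidic, x$Glu, x$Asp, x$basic, x$Arg, x$Lys, x$pI, x$notes))
  invisible(x)
}

#' Read sequences from a FASTA file
#'
#' Minimal FASTA reader returning named character strings (one per record).
#'
#' @param path path to a FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("not a FASTA file: no '>' header", call. = FALSE)
  idx <- cumsum(hdr)
  names_ <- sub("^>\\s*", "", lines[hdr])
  names_ <- vapply(strsplit(names_, "\\s+"), `[[`, character(1), 1L)
  seqs <- vapply(split(lines[!hdr], idx[!hdr]), paste0, character(1),
                 collapse = "")
  setNames(toupper(seqs), names_)
}

#' Write sequences to a FASTA file
#'
#' @param sequences named character vector.
#' @param path output path.
#' @param width line width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path, width = 60) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(sequences)) {
    writeLines(paste0(">", names(sequences)[i]), con)
    s <- sequences[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}
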