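# Accessors for the small reference resources shipped with the package.

#' Synthetic ACP-like reference sequence
#'
#' An 81-residue synthetic stand-in for a hyperthermophilic bacterial acyl
#' carrier protein. It is not a deposited sequence: it was constructed to
#' carry the residue identities and helix boundaries reported for the
#' hyperthermophilic ACP (e.g. R4, I15, the D39-S40-L41 motif, the helix III
#' residues D59/D62/L63/K65, Y75/I76/E77/K79) and the published charge
#' composition (10 Glu / 11 Asp, 1 Arg / 8 Lys), so that composition-level
#' statistics and the simulation presets are realistic.
#'
#' @return A single character string of length 81.
#' @export
acp_reference_sequence <- function() {
  unname(read_fasta(system.file("extdata", "tm_acp_like_synthetic.fasta",
                                package = "acpstab", mustWork = TRUE))[1L])
}

#' Published I15 side-chain contact distances
#'
#' The shortest proton-proton side-chain contact distances between the
#' central hydrophobic packing residue I15 and its eight partners, as printed
#' in the structure report of the hyperthermophilic ACP. These are data, not
#' recomputed values; use [closest_proton_contact()] to measure the same
#' quantity on coordinates.
#'
#' @return Data frame with columns `partner` and `distance_A`.
#' @export
i15_contact_distances <- function() {
  read.delim(system.file("extdata", "i15_contacts.tsv",
                         package = "acpstab", mustWork = TRUE),
             comment.char = "#", stringsAsFactors = FALSE)
}
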