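# Synthetic stand-ins for the two published validation pairs. Real PDB
# coordinates are not bundled; when the user has the PDB entries on disk the
# same analysis runs through read_pdb_chain() + align_structures() +
# shell_vs_rest() directly.

#' Synthetic stand-in for a published validation pair
#'
#' Builds a membrane protein / soluble counterpart pair whose planted
#' characteristics mirror one of the two published worked examples of
#' domain exchange:
#' \describe{
#'   \item{`"phosphatase"`}{a tyrosine-phosphatase-like exchange (membrane
#'     envelope factor vs a soluble low-molecular-weight phosphatase): a
#'     116-residue shared domain at 4.7% sequence identity with two
#'     conserved catalytic cysteines at positions 12 and 17 of the soluble
#'     chain.}
#'   \item{`"lactamase"`}{a penicillin-binding / beta-lactamase exchange:
#'     a 218-residue shared domain at 13.2% identity with a conserved
#'     Ser/Lys catalytic pair and conserved functional-site shells.}
#' }
#' These are generator products, not the real structures: they let the full
#' alignment / screening / shell machinery be exercised end to end at the
#' published problem sizes, but the absolute shell similarity scores of the
#' real coordinate pairs are not reproduced by construction.
#'
#' @param which `"phosphatase"` or `"lactamase"`.
#' @param seed RNG seed.
#' @return list with `mem` ([make_membrane_protein()] output), `sol`
#'   (counterpart with `structure`, `ss`, `sites`, truth `mapping`), and
#'   `planted` (list of the planted domain size and identity).
#' @export
synthetic_worked_pair <- function(which = c("phosphatase", "lactamase"),
                                  seed = 1L) {
  which <- match.arg(which)
  p <- switch(which,
    phosphatase = list(size = 116L, identity = 4.7, rmsd = 2.5,
                       sites_at = c(12L, 17L), site_aa = c("C", "C"),
                       shells = FALSE),
    lactamase = list(size = 218L, identity = 13.2, rmsd = 2.5,
                     sites_at = c(70L, 73L), site_aa = c("S", "K"),
                     shells = TRUE)
  )
  sp <- synthetic_spec(domain_size = p$size, seed = seed)
  mem <- make_membrane_protein(sp, id = paste0("synth_", which, "_mem_A"),
                               sites_at = p$sites_at, site_aa = p$site_aa)
  sol <- make_soluble_counterpart(
    mem, target_rmsd = p$rmsd, target_identity = p$identity,
    shell_conservation = p$shells,
    sites = if (p$shells) mem$sites,
    keep_identical = p$sites_at,
    seed = seed + 1L,
    id = paste0("synth_", which, "_sol_A")
  )
  dom_ss <- substr(mem$ss$ss, min(mem$domain_range), max(mem$domain_range))
  sol$ss <- ss_string(sol$structure$id, dom_ss)
  sol$sites <- functional_sites(sol$structure$id,
                                seq_num = p$sites_at, aa = p$site_aa)
  list(mem = mem, sol = sol,
       planted = list(domain_size = p$size, identity = p$identity,
                      rmsd = p$rmsd))
}
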