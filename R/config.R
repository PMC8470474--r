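#' Default analysis configuration
#'
#' All geometric thresholds used across the pipeline, in one place. Every
#' value can be overridden by passing a modified list to the functions that
#' take a `config` argument, or via the `--config` YAML file of the command
#' line interface. Distances are in Angstrom, angles in degrees.
#'
#' @param ... named overrides of individual keys. Unknown keys are rejected.
#'
#' @return a named list of thresholds:
#' \describe{
#'   \item{ca_ladder_dist}{max Ca-Ca distance for a strand ladder rung (ca_only mode).}
#'   \item{hbond_no_dist}{max N...O distance for a backbone hydrogen bond.}
#'   \item{hbond_donor_angle}{min donor angle (deg) for a backbone hydrogen bond.}
#'   \item{min_ladder_rungs}{min consecutive rungs for a ladder.}
#'   \item{min_strand_len}{min residues per strand (2 admits the I-set's short C').}
#'   \item{min_seq_sep}{min sequence separation between rung partners.}
#'   \item{extended_turn_max}{max Ca virtual-bond turn angle (deg) for a
#'     residue to count as extended; only extended residues join ladders.}
#'   \item{bulge_tolerance}{residues of interruption tolerated inside a strand.}
#'   \item{short_cprime_max}{max length (residues) of a "very short" C' (I-set rule).}
#'   \item{c2_angle_tol}{rotation angles within this of 180 deg count as C2.}
#'   \item{no_axis_angle}{rotations below this angle give a typed no-axis result.}
#'   \item{refine_pair_cutoff}{refinement pass drops pairs fitting worse than this.}
#'   \item{refine_max_rounds}{max refinement rounds.}
#'   \item{short_linker_max}{max protodomain linker length for parallel linkage (double Ig).}
#'   \item{inverter_min}{min linker length of the double-Ig inverter segment.}
#'   \item{interface_cutoff}{heavy-atom contact cutoff for dimer interfaces.}
#'   \item{attribution_majority}{fraction of contacts the top sheet needs (else "mixed").}
#'   \item{orient_parallel_max, orient_inverted_min}{G-strand angle bands for
#'     parallel / inverted dimer orientation; between them is "tilted".}
#'   \item{vdw_dist, hbond_dist, hbond_angle, ionic_dist, pi_stack_dist,
#'     pi_cation_dist, disulfide_dist}{interaction-typing cutoffs.}
#' }
#' @export
#' @examples
#' cfg <- igproto_config(ca_ladder_dist = 6.0)
#' cfg$ca_ladder_dist
igproto_config <- function(...) {
  cfg <- list(
    ca_ladder_dist       = 5.5,
    hbond_no_dist        = 3.5,
    hbond_donor_angle    = 120,
    min_ladder_rungs     = 2,
    min_strand_len       = 2,
    min_seq_sep          = 4,
    extended_turn_max    = 40,
    bulge_tolerance      = 1,
    short_cprime_max     = 3,
    c2_angle_tol         = 30,
    no_axis_angle        = 1,
    refine_pair_cutoff   = 3.5,
    refine_max_rounds    = 3,
    short_linker_max     = 5,
    inverter_min         = 10,
    interface_cutoff     = 4.5,
    attribution_majority = 0.6,
    orient_parallel_max  = 60,
    orient_inverted_min  = 120,
    vdw_dist             = 4.0,
    hbond_dist           = 3.8,
    hbond_angle          = 90,
    ionic_dist           = 6.0,
    pi_stack_dist        = 5.5,
    pi_cation_dist       = 6.0,
    disulfide_dist       = 2.5
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad))
      stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
    cfg[names(dots)] <- dots
  }
  cfg
}
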