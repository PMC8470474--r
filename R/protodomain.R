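# Protodomain decomposition and C2 superposition.
#
# An Ig domain is treated as a covalently linked dimer of two protodomains,
# AB-CC' and DE-FG: two beta-hairpins each, related by an internal ~180
# degree (C2) rotation. Decomposition takes whatever subset of the canonical
# strands is present in the topology at hand (e.g. no D in FN3-like domains).

.p_odd_labels  <- c("A", "A'", "B", "C", "C'")
.p_even_labels <- c("D", "E", "F", "G")
# symmetry-equivalent strand pairs (odd-protodomain label -> even-protodomain label)
.strand_pairs <- c("A" = "D", "B" = "E", "C" = "F", "C'" = "G")

#' Decompose an annotated Ig domain into protodomains
#'
#' Returns the two protodomains of a single Ig domain: p1 is the N-terminal
#' AB-CC' unit (whichever of A, A', B, C, C' are present), p2 the DE-FG unit.
#' The inter-protodomain linker interval is reported and named after its
#' flanking strands (e.g. the CDR2+C''+C''D linker of V-set domains, the C'D
#' linker of I-set domains, CD for cadherins, C'E for FN3).
#'
#' @param annotation an `IgAnnotation` with the BCEF core.
#' @return list of two objects of class `Protodomain`, each with `index`,
#'   `strand_labels`, `strands` (the labelled strand records), `residue_keys`,
#'   `sequence`, and `linker` (shared: the inter-protodomain interval).
#' @export
decompose <- function(annotation) {
  stopifnot(inherits(annotation, "IgAnnotation"))
  if (!isTRUE(annotation$is_ig))
    stop("cannot decompose: ", annotation$reason)
  lab <- annotation_labels(annotation)
  if (!all(c("E", "F") %in% lab))
    stop("decomposition failure: annotation lacks strand E or F")
  mk <- function(index, labels) {
    keep <- annotation$strands[lab %in% labels]
    keep <- keep[order(vapply(keep, function(s) min(s$idx), integer(1)))]
    protodomain_from_strands(index, keep,
                             vapply(keep, function(s) s$label, character(1)),
                             annotation$chain_id, annotation$det$trace)
  }
  p1 <- mk(1L, .p_odd_labels)
  p2 <- mk(2L, .p_even_labels)
  # linker between the protodomains, named by its flanking strands
  last1 <- p1$strands[[length(p1$strands)]]
  first2 <- p2$strands[[1]]
  trace <- annotation$det$trace
  a <- max(last1$idx); b <- min(first2$idx)
  linker <- list(name = paste0(last1$label, "-", first2$label),
                 interval = if (b - a >= 2) c(trace$resno[a + 1], trace$resno[b - 1]) else NULL)
  if ("C''" %in% lab) linker$name <- "CDR2+C''+C''D"
  p1$linker <- p2$linker <- linker
  list(p1, p2)
}

#' @export
print.Protodomain <- function(x, ...) {
  cat("Protodomain p", x$index, ": strands ",
      paste(x$strand_labels, collapse = "-"), " (", length(x$residue_keys),
      " residues)\n", sep = "")
  invisible(x)
}

# center-trim index pairing of two strands: trim the longer symmetrically to
# the shorter's length; an odd surplus keeps the window toward the N side.
trim_pair <- function(idx_a, idx_b) {
  la <- length(idx_a); lb <- length(idx_b)
  if (la > lb) {
    off <- floor((la - lb) / 2)
    idx_a <- idx_a[(off + 1):(off + lb)]
  } else if (lb > la) {
    off <- floor((lb - la) / 2)
    idx_b <- idx_b[(off + 1):(off + la)]
  }
  cbind(idx_a, idx_b)
}

#' Build the residue correspondence between two protodomains
#'
#' Pairs residues of symmetry-equivalent strands (A-D, B-E, C-F, C'-G):
#' each mapped strand pair is trimmed symmetrically around its center to the
#' shorter strand's length and paired index-by-index, both read N-to-C (the
#' C2 acts on the protodomain as a whole, so no antiparallel reversal is
#' applied). Loop residues are never paired. A-D is attempted only when a
#' strand literally labelled A exists in the first unit (an A' lying alone on
#' the G-side sheet is a symmetry-breaking remnant and stays unmatched).
#'
#' @param p_i,p_j `Protodomain` objects (or protodomain-like lists of labelled
#'   strands).
#' @param strands optional character vector restricting the mapped strand
#'   labels of `p_i` (e.g. `c("B","C","C'")` for a BCC' vs EFG match).
#' @param pair_map optional named character vector overriding the default
#'   strand-label pairing (names: labels in `p_i`; values: labels in `p_j`).
#' @return an object of class `ResidueCorrespondence`: data.frame `pairs`
#'   with the trace indices and residue keys of both members plus the strand
#'   pair, and attributes recording the mapping used.
#' @export
build_correspondence <- function(p_i, p_j, strands = NULL, pair_map = NULL) {
  labels_i <- vapply(p_i$strands, function(s) s$label, character(1))
  labels_j <- vapply(p_j$strands, function(s) s$label, character(1))
  if (is.null(pair_map)) {
    pair_map <- .strand_pairs
    pair_map <- pair_map[names(pair_map) %in% labels_i & pair_map %in% labels_j]
  }
  if (!is.null(strands)) pair_map <- pair_map[names(pair_map) %in% strands]
  if (length(pair_map) < 2)
    stop("no mappable strand pairs between the two protodomains")
  rows <- list()
  for (la in names(pair_map)) {
    sa <- p_i$strands[[which(labels_i == la)[1]]]
    sb <- p_j$strands[[which(labels_j == pair_map[[la]])[1]]]
    tp <- trim_pair(seq_along(sa$idx), seq_along(sb$idx))
    rows[[length(rows) + 1]] <- data.frame(
      strand_i = la, strand_j = pair_map[[la]],
      idx_i = sa$idx[tp[, 1]], idx_j = sb$idx[tp[, 2]],
      key_i = rkey(sa$resno[tp[, 1]], sa$ins[tp[, 1]]),
      key_j = rkey(sb$resno[tp[, 2]], sb$ins[tp[, 2]]),
      stringsAsFactors = FALSE)
  }
  pairs <- do.call(rbind, rows)
  structure(list(pairs = pairs, chain_i = p_i$chain_id, chain_j = p_j$chain_id,
                 trace_i = p_i$trace, trace_j = p_j$trace),
            class = "ResidueCorrespondence")
}

#' @export
print.ResidueCorrespondence <- function(x, ...) {
  cat("ResidueCorrespondence:", nrow(x$pairs), "residue pairs on strands",
      paste(unique(paste0(x$pairs$strand_i, "-", x$pairs$strand_j)), collapse = ", "), "\n")
  invisible(x)
}

corr_traces <- function(correspondence, structure) {
  tr_i <- correspondence$trace_i
  tr_j <- correspondence$trace_j
  if (is.null(tr_i)) tr_i <- extract_ca(structure, correspondence$chain_i)
  if (is.null(tr_j)) tr_j <- extract_ca(structure, correspondence$chain_j)
  list(i = tr_i, j = tr_j)
}

corr_xyz <- function(correspondence, structure) {
  tr <- corr_traces(correspondence, structure)
  list(x = tr$i$xyz[correspondence$pairs$idx_i, , drop = FALSE],
       y = tr$j$xyz[correspondence$pairs$idx_j, , drop = FALSE])
}

#' Superpose two protodomains under a residue correspondence
#'
#' Least-squares rigid superposition (reflection excluded) of the paired Ca
#' atoms; the RMSD is the root mean square of paired Ca distances after
#' fitting. With `refine = TRUE`, pairs fitting worse than
#' `config$refine_pair_cutoff` are dropped and the fit repeated (at most
#' `config$refine_max_rounds` rounds), emulating trimmed tool-style
#' alignments; the default is the plain all-pair fit.
#'
#' @param correspondence a `ResidueCorrespondence`.
#' @param structure the `StructureModel` the indices refer to.
#' @param refine logical; iterative worst-pair trimming (off by default).
#' @param config see [igproto_config()].
#' @return a `SuperpositionResult` (see [superpose_xyz()]); `pairs` carries
#'   the correspondence rows used in the final fit.
#' @export
superpose <- function(correspondence, structure, refine = FALSE,
                      config = igproto_config()) {
  xy <- corr_xyz(correspondence, structure)
  x <- xy$x; y <- xy$y
  keep <- seq_len(nrow(x))
  k <- kabsch(x, y)
  if (refine) {
    for (round in seq_len(config$refine_max_rounds)) {
      dev <- sqrt(rowSums((sweep(x[keep, , drop = FALSE] %*% t(k$rotation), 2,
                                 -k$translation) - y[keep, , drop = FALSE])^2))
      drop <- dev > config$refine_pair_cutoff
      if (!any(drop) || sum(!drop) < 3) break
      keep <- keep[!drop]
      k <- kabsch(x[keep, , drop = FALSE], y[keep, , drop = FALSE])
    }
  }
  new_superposition(k$rotation, k$translation, k$rmsd, length(keep),
                    centroids = list(colMeans(x[keep, , drop = FALSE]),
                                     colMeans(y[keep, , drop = FALSE])),
                    pairs = correspondence$pairs[keep, , drop = FALSE],
                    refined = refine)
}

#' Sequence identity over paired positions
#'
#' Reported for context only (protodomain identities sit in the twilight
#' zone); never used by the classifier.
#'
#' @param correspondence a `ResidueCorrespondence`.
#' @param structure the `StructureModel`.
#' @return fraction in [0, 1].
#' @export
paired_identity <- function(correspondence, structure) {
  tr <- corr_traces(correspondence, structure)
  a <- tr$i$resid[correspondence$pairs$idx_i]
  b <- tr$j$resid[correspondence$pairs$idx_j]
  mean(a == b)
}

#' Protodomain pseudosymmetry report for one annotated Ig domain
#'
#' Convenience wrapper: decompose, build the default correspondence, superpose
#' and extract the tertiary C2 axis.
#'
#' @param annotation an `IgAnnotation`.
#' @param structure the `StructureModel`.
#' @param strands,refine,config passed to the underlying steps.
#' @return list with `protodomains`, `correspondence`, `superposition`,
#'   `axis`, `identity`.
#' @export
protodomain_symmetry <- function(annotation, structure, strands = NULL,
                                 refine = FALSE, config = igproto_config()) {
  pd <- decompose(annotation)
  corr <- build_correspondence(pd[[1]], pd[[2]], strands = strands)
  sp <- superpose(corr, structure, refine = refine, config = config)
  ax <- symmetry_axis(sp, config = config)
  list(protodomains = pd, correspondence = corr, superposition = sp,
       axis = ax, identity = paired_identity(corr, structure))
}
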