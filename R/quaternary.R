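# Quaternary analysis of Ig-Ig dimers: interface sheet attribution, the
# quaternary C2 axis, parallel / inverted / tilted orientation, quasi-D2
# geometry, and protodomain-swap detection.

#' Reference an annotated Ig domain for quaternary analysis
#'
#' Bundles a chain (optionally a residue sub-range) with its strand annotation.
#'
#' @param structure a `StructureModel`.
#' @param chain_id chain identifier.
#' @param range optional closed residue interval in source numbering.
#' @param mode strand-detection mode.
#' @param override optional manual strand map, see [label_ig_strands()].
#' @param config see [igproto_config()].
#' @return an object of class `IgDomain`: list with `chain_id`, `range`,
#'   `annotation`, `det`.
#' @export
ig_domain <- function(structure, chain_id, range = NULL, mode = "ca_only",
                      override = NULL, config = igproto_config()) {
  det <- detect_strands_range(structure, chain_id, range, mode, config)
  ann <- label_ig_strands(det, override = override, config = config)
  structure(list(chain_id = chain_id, range = range, annotation = ann,
                 det = det), class = "IgDomain")
}

detect_strands_range <- function(structure, chain_id, range, mode, config) {
  if (is.null(range)) return(detect_strands(structure, chain_id, mode, config))
  at <- structure$atoms
  keep <- at$chain != chain_id | (at$resno >= range[1] & at$resno <= range[2])
  detect_strands(new_structure(at[keep, , drop = FALSE], structure$id),
                 chain_id, mode, config)
}

domain_atoms <- function(structure, dom) {
  at <- structure$atoms[structure$atoms$chain == dom$chain_id, , drop = FALSE]
  if (!is.null(dom$range))
    at <- at[at$resno >= dom$range[1] & at$resno <= dom$range[2], , drop = FALSE]
  at
}

# strand label (or "post-G"/"loop") for each residue key of a domain
residue_strand_map <- function(dom) {
  ann <- dom$annotation
  trace <- ann$det$trace
  lab <- rep("loop", nrow(trace$xyz))
  for (s in ann$strands) if (!is.na(s$label)) lab[s$idx] <- s$label
  g <- annotation_strand(ann, "G")
  if (!is.null(g) && max(g$idx) < length(lab))
    lab[(max(g$idx) + 1):length(lab)][
      lab[(max(g$idx) + 1):length(lab)] == "loop"] <- "post-G"
  stats::setNames(lab, rkey(trace$resno, trace$ins))
}

cross_min_dist <- function(A, B) {
  ax <- as.matrix(A[, c("x", "y", "z")]); bx <- as.matrix(B[, c("x", "y", "z")])
  d2 <- outer(rowSums(ax^2), rep(1, nrow(bx))) +
        outer(rep(1, nrow(ax)), rowSums(bx^2)) - 2 * ax %*% t(bx)
  sqrt(pmax(d2, 0))
}

#' Find and attribute an Ig-Ig dimer interface
#'
#' Contact residues are all residue pairs with any heavy-atom pair within
#' `cutoff`. Each partner's interface is attributed to a sheet or strand
#' group: the A'G/hinge category (contacts concentrated on A', G and post-G
#' residues, the CTLA-4/CD28-style cis interface), the C''D edge (CD86-style),
#' or the GFCC' vs ABED sheet by contact majority; below
#' `config$attribution_majority` of strand-resident contacts the attribution
#' is "mixed".
#'
#' @param structure a `StructureModel`.
#' @param domA,domB `IgDomain` references (chains may differ or be sub-ranges).
#' @param cutoff heavy-atom distance cutoff (default `config$interface_cutoff`).
#' @param config see [igproto_config()].
#' @return an object of class `DimerInterface`: `n_contacts`, per-partner
#'   `contact_residues` (data.frames), `attribution` (category + per-strand
#'   contact fractions), `empty` flag.
#' @export
find_interface <- function(structure, domA, domB, cutoff = NULL,
                           config = igproto_config()) {
  if (is.null(cutoff)) cutoff <- config$interface_cutoff
  A <- domain_atoms(structure, domA); B <- domain_atoms(structure, domB)
  D <- cross_min_dist(A, B)
  hit <- which(D <= cutoff, arr.ind = TRUE)
  if (nrow(hit) == 0)
    return(structure(list(empty = TRUE, n_contacts = 0,
                          contact_residues = NULL, attribution = NULL),
                     class = "DimerInterface"))
  keyA <- rkey(A$resno[hit[, 1]], A$ins[hit[, 1]])
  keyB <- rkey(B$resno[hit[, 2]], B$ins[hit[, 2]])
  attribute <- function(dom, keys) {
    smap <- residue_strand_map(dom)
    labs <- smap[keys]                      # one entry per atom contact
    labs[is.na(labs)] <- "loop"
    strandres <- labs[!labs %in% c("loop", "post-G")]
    frac_of <- function(set) if (length(labs)) mean(labs %in% set) else 0
    fr_strand <- if (length(strandres)) table(strandres) / length(strandres) else table(character(0))
    cat_frac <- function(set) if (length(strandres)) mean(strandres %in% set) else 0
    category <- if (frac_of(c("A'", "G", "post-G")) >= config$attribution_majority)
      "A'G_hinge"
    else if (cat_frac(c("C''", "D")) >= config$attribution_majority) "C''D"
    else {
      gf <- cat_frac(c("G", "F", "C", "C'")); ab <- cat_frac(c("A", "B", "E", "D"))
      if (max(gf, ab) >= config$attribution_majority)
        if (gf >= ab) "GFCC'" else "ABED"
      else "mixed"
    }
    list(category = category, strand_fractions = fr_strand)
  }
  uA <- !duplicated(keyA); uB <- !duplicated(keyB)
  structure(list(
    empty = FALSE, n_contacts = nrow(hit),
    contact_residues = list(
      A = data.frame(chain = domA$chain_id, key = keyA[uA],
                     resid = A$resid[hit[uA, 1]], stringsAsFactors = FALSE),
      B = data.frame(chain = domB$chain_id, key = keyB[uB],
                     resid = B$resid[hit[uB, 2]], stringsAsFactors = FALSE)),
    attribution = list(A = attribute(domA, keyA), B = attribute(domB, keyB))
  ), class = "DimerInterface")
}

#' @export
print.DimerInterface <- function(x, ...) {
  if (x$empty) { cat("DimerInterface: empty (no contacts within cutoff)\n"); return(invisible(x)) }
  cat("DimerInterface:", x$n_contacts, "atom contacts;",
      "attribution", x$attribution$A$category, "/", x$attribution$B$category, "\n")
  invisible(x)
}

domain_as_protounit <- function(dom) {
  ann <- dom$annotation
  keep <- ann$strands[!is.na(vapply(ann$strands, function(s) s$label, character(1)))]
  protodomain_from_strands(1L, keep, vapply(keep, function(s) s$label, character(1)),
                           dom$chain_id, trace = ann$det$trace)
}

#' Quaternary axis, orientation and quasi-D2 report of an Ig-Ig dimer
#'
#' The quaternary axis comes from superposing domain A onto domain B through a
#' label-matched strand correspondence. Orientation is the angle between the
#' two G-strand direction vectors (N-to-C): below
#' `config$orient_parallel_max` degrees is parallel (CDRs on the same side),
#' above `config$orient_inverted_min` inverted (G strands pointing opposite
#' ways), in between tilted. The D2 report compares each domain's tertiary
#' (protodomain) C2 axis with the partner's and with the quaternary axis, and
#' measures how far the tertiary axis points lie from the quaternary axis
#' (zero for an ideal quasi-D2 dimer).
#'
#' @param structure a `StructureModel`.
#' @param domA,domB `IgDomain` references.
#' @param config see [igproto_config()].
#' @return an object of class `DimerGeometry`: `quaternary_axis`,
#'   `quaternary_rmsd`, `orientation`, `g_angle`, `tertiary_axes`,
#'   `d2_report`, `partial` (TRUE when no label-matched correspondence
#'   exists).
#' @export
quaternary_axis_and_orientation <- function(structure, domA, domB,
                                            config = igproto_config()) {
  annA <- domA$annotation; annB <- domB$annotation
  stopifnot(isTRUE(annA$is_ig), isTRUE(annB$is_ig))
  gA <- annotation_strand(annA, "G"); gB <- annotation_strand(annB, "G")
  g_angle <- if (!is.null(gA) && !is.null(gB))
    vec_angle(strand_direction(gA, annA$det$trace),
              strand_direction(gB, annB$det$trace)) else NA_real_
  orientation <- if (is.na(g_angle)) "unknown"
    else if (g_angle < config$orient_parallel_max) "parallel"
    else if (g_angle > config$orient_inverted_min) "inverted"
    else "tilted"
  tA <- protodomain_symmetry(annA, structure, config = config)
  tB <- protodomain_symmetry(annB, structure, config = config)
  uA <- domain_as_protounit(domA); uB <- domain_as_protounit(domB)
  shared <- intersect(uA$strand_labels, uB$strand_labels)
  quaternary <- NULL; q_rmsd <- NA_real_; partial <- FALSE
  if (length(shared) >= 2) {
    corr <- build_correspondence(uA, uB, pair_map = stats::setNames(shared, shared))
    spq <- superpose(corr, structure, config = config)
    quaternary <- symmetry_axis(spq, config = config)
    q_rmsd <- spq$rmsd
  } else partial <- TRUE
  d2 <- NULL
  if (!is.null(quaternary) && isTRUE(quaternary$found) &&
      isTRUE(tA$axis$found) && isTRUE(tB$axis$found)) {
    d2 <- list(
      tertiary_tertiary_angle = line_angle(tA$axis$direction, tB$axis$direction),
      tertiary_quaternary_angle = c(
        A = line_angle(tA$axis$direction, quaternary$direction),
        B = line_angle(tB$axis$direction, quaternary$direction)),
      center_offset = max(
        line_line_dist(tA$axis$point, tA$axis$direction,
                       quaternary$point, quaternary$direction),
        line_line_dist(tB$axis$point, tB$axis$direction,
                       quaternary$point, quaternary$direction)))
  }
  structure(list(quaternary_axis = quaternary, quaternary_rmsd = q_rmsd,
                 orientation = orientation, g_angle = g_angle,
                 tertiary_axes = list(A = tA$axis, B = tB$axis),
                 d2_report = d2, partial = partial),
            class = "DimerGeometry")
}

#' @export
print.DimerGeometry <- function(x, ...) {
  cat("DimerGeometry:", x$orientation,
      sprintf("(G-strand angle %.1f deg)", x$g_angle), "\n")
  if (!is.null(x$quaternary_axis) && x$quaternary_axis$found)
    cat(sprintf("  quaternary axis angle %.1f deg, rmsd %.3f A\n",
                x$quaternary_axis$angle, x$quaternary_rmsd))
  if (!is.null(x$d2_report))
    cat(sprintf("  D2: tertiary/tertiary %.1f deg, tertiary/quaternary %.1f & %.1f deg, center offset %.2f A\n",
                x$d2_report$tertiary_tertiary_angle,
                x$d2_report$tertiary_quaternary_angle[1],
                x$d2_report$tertiary_quaternary_angle[2],
                x$d2_report$center_offset))
  invisible(x)
}

# longest ladder run between two Ca coordinate sets (usable across chains)
cross_ladder_run <- function(xyzA, xyzB, max_dist) {
  D <- cross_min_dist(data.frame(x = xyzA[, 1], y = xyzA[, 2], z = xyzA[, 3]),
                      data.frame(x = xyzB[, 1], y = xyzB[, 2], z = xyzB[, 3]))
  hit <- D <= max_dist
  if (!any(hit)) return(0L)
  best <- 0L
  n <- nrow(hit); m <- ncol(hit)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    if (!hit[i, j]) next
    for (dj in c(-1L, 1L)) {
      len <- 1L; ii <- i + 1L; jj <- j + dj
      while (ii <= n && jj >= 1 && jj <= m && hit[ii, jj]) {
        len <- len + 1L; ii <- ii + 1L; jj <- jj + dj
      }
      best <- max(best, len)
    }
  }
  best
}

# Protodomain-like unit segmentation for the swap detector. Canonical chains
# are decomposed through their annotation. Swapped chains cannot be annotated
# alone (the core straddle spans both chains, so single-chain detection leaves
# their strands truncated); in that case strands are detected on a merged
# two-chain view -- where the cross-chain ladders complete them -- and each
# chain's strands are cut into its AB-CC' and DE-FG units at the longest
# linker.
swap_units <- function(structure, chainA, chainB, mode, config) {
  one <- function(chain_id) {
    ann <- tryCatch(label_ig_strands(detect_strands(structure, chain_id, mode, config),
                                     config = config), error = function(e) NULL)
    if (!is.null(ann) && isTRUE(ann$is_ig)) {
      pd <- decompose(ann)
      list(p_odd = pd[[1]], p_even = pd[[2]], via = "annotation")
    } else NULL
  }
  uA <- one(chainA); uB <- one(chainB)
  if (!is.null(uA) && !is.null(uB)) return(list(A = uA, B = uB))
  # merged two-chain view
  atA <- structure$atoms[structure$atoms$chain == chainA, , drop = FALSE]
  atB <- structure$atoms[structure$atoms$chain == chainB, , drop = FALSE]
  off <- max(atA$resno) + 60L
  atB$resno <- atB$resno + off
  m <- rbind(atA, atB); m$chain <- "M"
  det <- detect_strands(new_structure(m, structure$id), "M", mode, config)
  from_B <- vapply(det$strands, function(s) min(s$resno) > off - 30, logical(1))
  cut_units <- function(ks, chain_id, resno_offset) {
    ns <- length(ks)
    if (ns < 6) stop("chain ", chain_id, " not decomposable into protodomains")
    starts <- vapply(det$strands[ks], function(s) min(s$idx), integer(1))
    ends <- vapply(det$strands[ks], function(s) max(s$idx), integer(1))
    gaps <- starts[-1] - ends[-ns] - 1
    valid <- which(seq_len(ns - 1) >= 3 & (ns - seq_len(ns - 1)) >= 3)
    if (!length(valid)) stop("chain ", chain_id, " not decomposable into protodomains")
    cut <- valid[which.max(gaps[valid])]
    odd <- ks[seq_len(cut)]; even <- ks[(cut + 1):ns]
    if (length(odd) > 5) odd <- odd[(length(odd) - 4):length(odd)]
    if (length(even) > 4) even <- even[1:4]
    lo <- switch(as.character(length(odd)),
      "5" = c("A", "A'", "B", "C", "C'"), "4" = c("A'", "B", "C", "C'"),
      "3" = c("B", "C", "C'"), NULL)
    le <- switch(as.character(length(even)),
      "4" = c("D", "E", "F", "G"), "3" = c("E", "F", "G"), NULL)
    if (is.null(lo) || is.null(le))
      stop("chain ", chain_id, " not decomposable into protodomains (",
           length(odd), "+", length(even), " strands)")
    list(p_odd = protodomain_from_strands(1L, det$strands[odd], lo, chain_id, det$trace),
         p_even = protodomain_from_strands(2L, det$strands[even], le, chain_id, det$trace),
         via = "merged-view segmentation", resno_offset = resno_offset)
  }
  list(A = cut_units(which(!from_B), chainA, 0L),
       B = cut_units(which(from_B), chainB, off))
}

# Domain-closure evidence between an AB-CC' unit and a DE-FG unit: total
# ladder rungs between any strand pair of the two units. A closed Ig core
# interleaves the units through its lateral B|E and C|F ladders; units from
# different spatial domains share no ladder at all. Label-agnostic on purpose:
# strand labels inside swapped chains can be shifted when single-chain
# detection truncates strands whose ladder partner lives in the other chain.
closure_ok <- function(p_odd, p_even, config) {
  mr <- config$min_ladder_rungs
  total <- 0L
  ladders <- character(0)
  for (sa in p_odd$strands) for (sb in p_even$strands) {
    r <- cross_ladder_run(p_odd$trace$xyz[sa$idx, , drop = FALSE],
                          p_even$trace$xyz[sb$idx, , drop = FALSE],
                          config$ca_ladder_dist)
    if (r >= mr) {
      total <- total + r
      ladders <- c(ladders, sprintf("%s|%s:%d", sa$label, sb$label, r))
    }
  }
  list(ok = total >= 2 * mr, total_rungs = total, ladders = ladders)
}

#' Detect a protodomain-swapped Ig dimer (CD2 style)
#'
#' Two sequence units (chains) are swapped when the spatial Ig domains are
#' closed by the cross pairs -- unit A's AB-CC' with unit B's DE-FG and vice
#' versa (each closing the lateral B|E and C|F ladders of an Ig core) -- while
#' the sequential pairs within each unit fail domain closure. Canonical
#' domains close sequentially; anything else is reported indeterminate.
#'
#' @param structure a `StructureModel`.
#' @param chainA,chainB the two sequence units.
#' @param mode strand-detection mode.
#' @param config see [igproto_config()].
#' @return an object of class `SwapReport`: `swapped` (TRUE/FALSE/NA),
#'   `status`, per-pairing closure evidence, and the linker intervals between
#'   each unit's protodomains.
#' @export
detect_protodomain_swap <- function(structure, chainA, chainB,
                                    mode = "ca_only", config = igproto_config()) {
  units <- swap_units(structure, chainA, chainB, mode, config)
  uA <- units$A; uB <- units$B
  seqA <- closure_ok(uA$p_odd, uA$p_even, config)
  seqB <- closure_ok(uB$p_odd, uB$p_even, config)
  crossAB <- closure_ok(uA$p_odd, uB$p_even, config)
  crossBA <- closure_ok(uB$p_odd, uA$p_even, config)
  seq_ok <- seqA$ok && seqB$ok
  cross_ok <- crossAB$ok && crossBA$ok
  swapped <- if (cross_ok && !seq_ok) TRUE else if (seq_ok && !cross_ok) FALSE else NA
  linker_of <- function(u) {
    a <- max(u$p_odd$strands[[length(u$p_odd$strands)]]$idx)
    b <- min(u$p_even$strands[[1]]$idx)
    tr <- u$p_odd$trace
    off <- u$resno_offset %||% 0L
    if (b - a >= 2) c(tr$resno[a + 1], tr$resno[b - 1]) - off else NULL
  }
  structure(list(
    swapped = swapped,
    status = if (isTRUE(swapped)) "swapped" else if (isFALSE(swapped)) "canonical"
             else "indeterminate",
    closures = list(sequential_A = seqA, sequential_B = seqB,
                    cross_A_odd_B_even = crossAB, cross_B_odd_A_even = crossBA),
    evidence = c(sequential = min(seqA$total_rungs, seqB$total_rungs),
                 cross = min(crossAB$total_rungs, crossBA$total_rungs)),
    linkers = list(A = linker_of(uA), B = linker_of(uB))
  ), class = "SwapReport")
}

#' @export
print.SwapReport <- function(x, ...) {
  cat("SwapReport:", x$status, "\n")
  invisible(x)
}
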