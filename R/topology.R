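# Topology classification of Ig(-like) domains.
#
# The classes are distinguished purely by which lateral strands exist and on
# which sheet the N-terminal strand lies; the C2-set vs FN3 tie (identical
# strand tables) is broken by the CCW(L) sequence signature: the pair of
# buried cysteines on strands B and F (the intra-domain disulfide), the
# tryptophan on C and the leucine on E.

#' Detect the CCW(L) signature
#'
#' Scans strands B, C, E and F (each widened by one flanking residue) for
#' their signature residues: Cys on B, Trp on C, Leu on E (Ile/Val/Met
#' accepted as a conservative fallback and flagged), Cys on F.
#'
#' @param annotation an `IgAnnotation` with B, C, E, F labelled.
#' @return an object of class `SignatureHit`: `positions` (named list of
#'   residue keys or `NA`), `strict` (named logical; fallback hits are
#'   non-strict), `n_strict`, `complete` (all four strict).
#' @export
detect_ccwl <- function(annotation) {
  stopifnot(inherits(annotation, "IgAnnotation"))
  trace <- annotation$det$trace
  spec <- list(C_in_B = list("B", "CYS", character(0)),
               W_in_C = list("C", "TRP", character(0)),
               L_in_E = list("E", "LEU", c("ILE", "VAL", "MET")),
               C_in_F = list("F", "CYS", character(0)))
  positions <- list(); strict <- logical(0)
  for (nm in names(spec)) {
    s <- annotation_strand(annotation, spec[[nm]][[1]])
    positions[[nm]] <- NA_character_; strict[nm] <- FALSE
    if (is.null(s)) next
    idx <- max(1, min(s$idx) - 1):min(nrow(trace$xyz), max(s$idx) + 1)
    res <- trace$resid[idx]
    hit <- which(res == spec[[nm]][[2]])
    if (length(hit)) {
      positions[[nm]] <- rkey(trace$resno[idx[hit[1]]], trace$ins[idx[hit[1]]])
      strict[nm] <- TRUE
    } else if (length(spec[[nm]][[3]])) {
      fb <- which(res %in% spec[[nm]][[3]])
      if (length(fb))
        positions[[nm]] <- rkey(trace$resno[idx[fb[1]]], trace$ins[idx[fb[1]]])
    }
  }
  structure(list(positions = positions, strict = strict,
                 n_strict = sum(strict), complete = all(strict)),
            class = "SignatureHit")
}

#' @export
print.SignatureHit <- function(x, ...) {
  cat("SignatureHit CCW(L):", x$n_strict, "of 4 strict;",
      if (x$complete) "complete" else "incomplete", "\n")
  invisible(x)
}

#' Classify the topology of an annotated Ig domain
#'
#' Applies the strand-presence decision rules in a fixed, total order and
#' records every test in the rule trace:
#' \enumerate{
#'   \item C'' present: V-set (the only class with a C'' strand).
#'   \item no C'', short C' (at most `config$short_cprime_max` residues) and a
#'     split A/A': I-set (reported as VNAR-like only under the optional
#'     hydrophilicity heuristic, `vnar_heuristic = TRUE`).
#'   \item no C', A entirely on the ABED sheet: C1-set.
#'   \item no C', the N-terminal strand entirely on the GFC sheet: cadherin.
#'   \item no D: C2-set when the CCW(L) signature has >= 3 strict hits,
#'     else FN3 (the two share the strand table).
#'   \item otherwise: not Ig (including annotations without the core straddle).
#' }
#'
#' @param annotation an `IgAnnotation`.
#' @param config see [igproto_config()].
#' @param vnar_heuristic logical; when `TRUE`, an I-set whose G/F/C/C' strands
#'   are mostly hydrophilic is flagged VNAR-like. Heuristic only.
#' @return an object of class `TopologyClass`: `label`, `rule_trace`
#'   (character), `signature` (the `SignatureHit`), `notes`.
#' @export
classify_topology <- function(annotation, config = igproto_config(),
                              vnar_heuristic = FALSE) {
  stopifnot(inherits(annotation, "IgAnnotation"))
  trace <- character(0); notes <- character(0)
  verdict <- function(label, signature = NULL)
    structure(list(label = label, rule_trace = trace, signature = signature,
                   notes = notes), class = "TopologyClass")
  if (!isTRUE(annotation$is_ig)) {
    trace <- c(trace, paste0("core straddle: absent (", annotation$reason, ") -> not_Ig"))
    return(verdict("not_Ig"))
  }
  lab <- annotation_labels(annotation)
  has <- function(l) l %in% lab
  slen <- function(l) { s <- annotation_strand(annotation, l); if (is.null(s)) 0L else length(s$idx) }
  sig <- detect_ccwl(annotation)

  trace <- c(trace, paste0("rule 1 (C'' present -> V_set): ", has("C''")))
  if (has("C''")) return(verdict("V_set", sig))

  r2 <- has("C'") && slen("C'") <= config$short_cprime_max && isTRUE(annotation$a_split)
  trace <- c(trace, paste0("rule 2 (short C' <= ", config$short_cprime_max,
                           " and split A/A' -> I_set): ", r2))
  if (r2) {
    if (vnar_heuristic) {
      hyd <- c("ASP", "GLU", "LYS", "ARG", "ASN", "GLN", "SER", "THR", "HIS")
      res <- unlist(lapply(c("G", "F", "C", "C'"), function(l) {
        s <- annotation_strand(annotation, l); if (is.null(s)) NULL else s$resid
      }))
      frac <- mean(res %in% hyd)
      notes <- c(notes, sprintf("VNAR hydrophilicity heuristic: %.2f hydrophilic on GFCC'", frac))
      if (frac > 0.5) { trace <- c(trace, "VNAR heuristic fired"); return(verdict("VNAR_like", sig)) }
    }
    return(verdict("I_set", sig))
  }

  r3 <- !has("C'") && has("A")
  trace <- c(trace, paste0("rule 3 (no C', A on the ABED sheet -> C1_set): ", r3))
  if (r3) return(verdict("C1_set", sig))

  r4 <- !has("C'") && has("A'") && !has("A")
  trace <- c(trace, paste0("rule 4 (no C', A only on the GFC sheet -> cadherin): ", r4))
  if (r4) return(verdict("cadherin", sig))

  r5 <- !has("D")
  trace <- c(trace, paste0("rule 5 (no D -> C2_set/FN3): ", r5))
  if (r5) {
    trace <- c(trace, paste0("CCW(L) strict hits: ", sig$n_strict, "/4 (>=3 -> C2_set)"))
    return(verdict(if (sig$n_strict >= 3) "C2_set" else "FN3", sig))
  }

  trace <- c(trace, "rule 6: no class rule fired -> not_Ig")
  notes <- c(notes, "full strand table without a class rule (possible swapped/AB-exchanged architecture)")
  verdict("not_Ig", sig)
}

#' @export
print.TopologyClass <- function(x, ...) {
  cat("TopologyClass:", x$label, "\n")
  for (t in x$rule_trace) cat("  -", t, "\n")
  invisible(x)
}

# build a Protodomain object from a set of already-detected strands
protodomain_from_strands <- function(index, strands, labels, chain_id, trace = NULL) {
  for (k in seq_along(strands)) strands[[k]]$label <- labels[k]
  seq1 <- paste(unlist(lapply(strands, function(s) {
    a <- .aa3to1[s$resid]; a[is.na(a)] <- "X"; a
  })), collapse = "")
  structure(list(index = index, strand_labels = labels, strands = strands,
                 residue_keys = unlist(lapply(strands, function(s) rkey(s$resno, s$ins))),
                 sequence = seq1, chain_id = chain_id, trace = trace),
            class = "Protodomain")
}

strand_direction <- function(s, trace) {
  xyz <- trace$xyz[s$idx, , drop = FALSE]
  unit(xyz[nrow(xyz), ] - xyz[1, ])
}

rungs_between <- function(det, a, b) {
  hit <- (det$adjacency$s1 == a & det$adjacency$s2 == b) |
         (det$adjacency$s1 == b & det$adjacency$s2 == a)
  if (any(hit)) det$adjacency$n_rungs[which(hit)[1]] else 0L
}

#' Detect a CD19-style interdigitated double Ig fold
#'
#' Scans one chain for the double-Ig architecture: four protodomains in two
#' parallel-linked pairs (p1-p2 and p3-p4, each joined by a short linker that
#' leaves their B and E strands parallel), separated by a long inverter
#' segment, with the two halves' sheets fused laterally through C'|C' and D|D
#' ladders. The two composite Ig domains are derived: (p1,p4) regular and
#' (p2,p3) inverse -- inverse because its DE-FG member precedes its AB-CC'
#' member in sequence, a circular permutation realized by folding. Local C2
#' axes of both composites and the central C2 axis relating the two halves are
#' computed.
#'
#' @param structure a `StructureModel`.
#' @param chain_id chain to scan.
#' @param mode strand-detection mode, see [detect_strands()].
#' @param config see [igproto_config()].
#' @return an object of class `DoubleIgScan`: `found` (logical), `model` (a
#'   `DoubleIgModel` or `NULL`), `diagnostic` (character vector listing which
#'   evidence failed). The `DoubleIgModel` carries `protodomains` (p1..p4),
#'   `parallel_pairs` (linker intervals and B/E angles), `inverter_linker`,
#'   `composite_domains` with the inverse flag, `fused_sheet_evidence` (rung
#'   counts on C'|C' and D|D), and `axes` (local p1-p4, local p2-p3, central).
#' @export
detect_double_ig <- function(structure, chain_id, mode = "ca_only",
                             config = igproto_config()) {
  det <- detect_strands(structure, chain_id, mode = mode, config = config)
  scan <- function(found, model = NULL, diagnostic = character(0))
    structure(list(found = found, model = model, diagnostic = diagnostic),
              class = "DoubleIgScan")
  ns <- length(det$strands)
  if (ns < 16)
    return(scan(FALSE, diagnostic = sprintf(
      "fewer than 16 strands (%d): not four protodomain-like units", ns)))
  trace <- det$trace
  starts <- vapply(det$strands, function(s) min(s$idx), integer(1))
  ends <- vapply(det$strands, function(s) max(s$idx), integer(1))
  gaps <- starts[-1] - ends[-ns] - 1
  kinv <- which.max(gaps)
  diag <- character(0)
  if (gaps[kinv] <= config$inverter_min)
    diag <- c(diag, sprintf("(b) no inverter segment: longest linker %d residues (need > %d)",
                            gaps[kinv], config$inverter_min))
  half1 <- seq_len(kinv); half2 <- (kinv + 1):ns
  if (length(half1) < 8 || length(half2) < 8)
    return(scan(FALSE, diagnostic = c(diag, sprintf(
      "halves of %d and %d strands: need 8 (A'BCC' + DEFG) each",
      length(half1), length(half2)))))
  units <- list(half1[1:4], half1[5:8], half2[1:4], half2[5:8])
  plabs <- list(c("A'", "B", "C", "C'"), c("D", "E", "F", "G"),
                c("A'", "B", "C", "C'"), c("D", "E", "F", "G"))
  pd <- lapply(1:4, function(u)
    protodomain_from_strands(u, det$strands[units[[u]]], plabs[[u]], chain_id,
                             trace = trace))
  # (a) short parallel linkers within each half
  linkers <- list()
  for (h in c(1, 3)) {
    lastk <- units[[h]][4]; firstk <- units[[h + 1]][1]
    gap <- starts[firstk] - ends[lastk] - 1
    angBE <- vec_angle(strand_direction(det$strands[[units[[h]][2]]], trace),
                       strand_direction(det$strands[[units[[h + 1]][2]]], trace))
    if (gap > config$short_linker_max)
      diag <- c(diag, sprintf("(a) p%d-p%d linker is %d residues (need <= %d)",
                              h, h + 1, gap, config$short_linker_max))
    if (angBE >= 90)
      diag <- c(diag, sprintf("(a) p%d/p%d B-E strand angle %.0f deg: not parallel", h, h + 1, angBE))
    linkers[[length(linkers) + 1]] <- list(
      pair = c(h, h + 1), length = gap, b_e_angle = angBE,
      interval = c(trace$resno[ends[lastk] + 1], trace$resno[starts[firstk] - 1]))
  }
  # (c) fused sheets: lateral ladders C'1|C'2 and D1|D2
  n_cc <- rungs_between(det, units[[1]][4], units[[3]][4])
  n_dd <- rungs_between(det, units[[2]][1], units[[4]][1])
  if (n_cc < config$min_ladder_rungs)
    diag <- c(diag, sprintf("(c) C'|C' fusion: %d rungs (need >= %d)", n_cc, config$min_ladder_rungs))
  if (n_dd < config$min_ladder_rungs)
    diag <- c(diag, sprintf("(c) D|D fusion: %d rungs (need >= %d)", n_dd, config$min_ladder_rungs))
  if (length(diag)) return(scan(FALSE, diagnostic = diag))

  inverter <- c(trace$resno[ends[kinv] + 1], trace$resno[starts[kinv + 1] - 1])
  # composite Ig domains: (p1,p4) regular; (p2,p3) inverse (DE-FG precedes AB-CC')
  corr14 <- build_correspondence(pd[[1]], pd[[4]])
  corr32 <- build_correspondence(pd[[3]], pd[[2]])
  sp14 <- superpose(corr14, structure, config = config)
  sp32 <- superpose(corr32, structure, config = config)
  # central C2: half1 onto half2, label-matched (p1<->p3, p2<->p4)
  idm <- function(p) stats::setNames(p$strand_labels, p$strand_labels)
  corr13 <- build_correspondence(pd[[1]], pd[[3]], pair_map = idm(pd[[1]]))
  corr24 <- build_correspondence(pd[[2]], pd[[4]], pair_map = idm(pd[[2]]))
  central_corr <- structure(list(pairs = rbind(corr13$pairs, corr24$pairs),
                                 chain_i = chain_id, chain_j = chain_id,
                                 trace_i = trace, trace_j = trace),
                            class = "ResidueCorrespondence")
  sp_c <- superpose(central_corr, structure, config = config)
  model <- structure(list(
    protodomains = pd,
    parallel_pairs = linkers,
    inverter_linker = inverter,
    composite_domains = list(
      regular = list(members = c(1, 4), inverse = FALSE,
                     superposition = sp14, axis = symmetry_axis(sp14, config = config)),
      inverse = list(members = c(2, 3), inverse = TRUE,
                     superposition = sp32, axis = symmetry_axis(sp32, config = config))),
    fused_sheet_evidence = list(c_prime = n_cc, d = n_dd),
    axes = list(local_p1_p4 = symmetry_axis(sp14, config = config),
                local_p2_p3 = symmetry_axis(sp32, config = config),
                central = symmetry_axis(sp_c, config = config)),
    central_superposition = sp_c,
    det = det, chain_id = chain_id
  ), class = "DoubleIgModel")
  scan(TRUE, model = model)
}

#' @export
print.DoubleIgScan <- function(x, ...) {
  if (x$found) cat("DoubleIgScan: double Ig fold detected\n")
  else cat("DoubleIgScan: not a double Ig fold\n ",
           paste(x$diagnostic, collapse = "\n  "), "\n")
  invisible(x)
}

#' @export
print.DoubleIgModel <- function(x, ...) {
  cat("DoubleIgModel: 4 protodomains; composite Ig domains (p1,p4) regular,",
      "(p2,p3) inverse\n")
  cat(sprintf("  central C2 angle %.1f deg; fused ladders C'|C' %d rungs, D|D %d rungs\n",
              x$axes$central$angle, x$fused_sheet_evidence$c_prime,
              x$fused_sheet_evidence$d))
  invisible(x)
}

.strand_color <- c("A" = "blue", "D" = "blue", "B" = "green", "E" = "green",
                   "C" = "yellow", "F" = "yellow", "C'" = "orange",
                   "G" = "orange", "A'" = "orange", "C''" = "red")

#' Topology / sequence map of an annotated domain
#'
#' Renders both sheets as rows of strands in lateral order, residues placed by
#' ladder register (one column per register position; sequential packing with
#' a flag when registers are missing), with loop names and the protodomain
#' color classes (A/D blue, B/E green, C/F yellow, C'/G orange, C'' red).
#' For a double Ig fold the map shows the two fused long sheets, strand labels
#' suffixed with their protodomain index (e.g. C'1, C'2).
#'
#' @param x an `IgAnnotation` (labelled) or a `DoubleIgModel`.
#' @return an object of class `TopologyMap`: list of sheets, each a list of
#'   strand rows (`label`, `color`, `keys`, `letters`, `cols`), plus `loops`;
#'   printable as a plain-text grid and serializable to JSON.
#' @export
topology_map <- function(x) UseMethod("topology_map")

#' @export
topology_map.IgAnnotation <- function(x) {
  stopifnot(isTRUE(x$is_ig))
  det <- x$det
  for (k in seq_along(det$strands)) det$strands[[k]]$label <- x$strands[[k]]$label
  structure(list(sheets = map_sheets(det), loops = x$loops,
                 chain_id = x$chain_id), class = "TopologyMap")
}

#' @export
topology_map.DoubleIgModel <- function(x) {
  det <- x$det
  # label detected strands from the protodomain units (suffix = unit index)
  lab <- stats::setNames(rep(NA_character_, length(det$strands)),
                         seq_along(det$strands))
  for (p in x$protodomains) for (s in p$strands)
    for (k in seq_along(det$strands))
      if (identical(det$strands[[k]]$idx, s$idx))
        det$strands[[k]]$label <- paste0(s$label, p$index)
  structure(list(sheets = map_sheets(det, strip_suffix = TRUE),
                 loops = list(inverter = x$inverter_linker),
                 chain_id = x$chain_id), class = "TopologyMap")
}

map_sheets <- function(det, strip_suffix = FALSE) {
  sheets <- list()
  for (sid in unique(det$sheet_ids)) {
    ks <- which(det$sheet_ids == sid)
    if (length(ks) < 2) next
    sheets[[length(sheets) + 1]] <- place_sheet(det, ks, strip_suffix)
  }
  sheets
}

# assign register-based columns to the strands of one sheet via BFS over
# the adjacency registers
place_sheet <- function(det, ks, strip_suffix = FALSE) {
  trace <- det$trace
  # lateral order: walk the adjacency graph from an edge strand
  nbrs <- lapply(ks, function(a) {
    hit <- det$adjacency$s1 == a | det$adjacency$s2 == a
    nb <- unique(c(det$adjacency$s1[hit], det$adjacency$s2[hit]))
    intersect(setdiff(nb, a), ks)
  })
  names(nbrs) <- ks
  deg <- vapply(nbrs, length, integer(1))
  start <- ks[which(deg <= 1)[1]]
  if (!is.na(start)) {
    path <- start; cur <- start
    while (TRUE) {
      nxt <- setdiff(nbrs[[as.character(cur)]], path)
      if (!length(nxt)) break
      cur <- nxt[1]; path <- c(path, cur)
    }
    if (length(path) == length(ks)) ks <- path
  }
  cols <- list(); fallback <- FALSE
  anchor <- ks[which.max(vapply(det$strands[ks], function(s) length(s$idx), integer(1)))]
  cols[[as.character(anchor)]] <- seq_along(det$strands[[anchor]]$idx)
  done <- anchor; queue <- anchor
  while (length(queue)) {
    a <- queue[1]; queue <- queue[-1]
    for (b in ks[!ks %in% done]) {
      key <- paste(min(a, b), max(a, b), sep = "|")
      reg <- det$registers[[key]]
      if (is.null(reg)) next
      sa <- det$strands[[a]]; sb <- det$strands[[b]]
      ia <- match(paste(reg$resno_i, reg$ins_i), paste(sa$resno, sa$ins))
      ib <- match(paste(reg$resno_j, reg$ins_j), paste(sb$resno, sb$ins))
      if (min(a, b) != a) { tmp <- ia; ia <- ib; ib <- tmp }
      ok <- !is.na(ia) & !is.na(ib)
      if (!any(ok)) next
      anti <- reg$orientation[1] == "antiparallel"
      offs <- if (anti) cols[[as.character(a)]][ia[ok]] + ib[ok]
              else cols[[as.character(a)]][ia[ok]] - ib[ok]
      off <- round(stats::median(offs))
      cols[[as.character(b)]] <- if (anti) off - seq_along(sb$idx) else off + seq_along(sb$idx)
      done <- c(done, b); queue <- c(queue, b)
    }
  }
  for (b in ks[!ks %in% done]) {   # unplaced: sequential packing, flagged
    cols[[as.character(b)]] <- seq_along(det$strands[[b]]$idx)
    fallback <- TRUE
  }
  rows <- lapply(ks, function(k) {
    s <- det$strands[[k]]
    aa <- .aa3to1[s$resid]; aa[is.na(aa)] <- "X"
    lb <- if (is.na(s$label)) paste0("s", k) else s$label
    base_label <- if (strip_suffix) sub("[0-9]+$", "", lb) else lb
    list(label = lb, color = unname(.strand_color[base_label]),
         keys = rkey(s$resno, s$ins), letters = aa,
         cols = cols[[as.character(k)]])
  })
  attr(rows, "fallback") <- fallback
  rows
}

#' @export
format.TopologyMap <- function(x, ...) {
  out <- character(0)
  for (i in seq_along(x$sheets)) {
    rows <- x$sheets[[i]]
    allc <- unlist(lapply(rows, `[[`, "cols"))
    lo <- min(allc); hi <- max(allc)
    out <- c(out, sprintf("sheet %d:", i))
    for (r in rows) {
      line <- rep(" ", hi - lo + 1)
      line[r$cols - lo + 1] <- r$letters
      out <- c(out, sprintf("  %-4s %s", r$label, paste(line, collapse = "")))
    }
  }
  lp <- x$loops[!vapply(x$loops, is.null, logical(1))]
  if (length(lp))
    out <- c(out, paste("loops:", paste(sprintf("%s %s-%s", names(lp),
      vapply(lp, `[`, numeric(1), 1), vapply(lp, `[`, numeric(1), 2)), collapse = ", ")))
  out
}

#' @export
print.TopologyMap <- function(x, ...) {
  cat(format(x), sep = "\n")
  invisible(x)
}
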