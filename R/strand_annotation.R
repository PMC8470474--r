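# Beta-strand / beta-sheet detection and canonical Ig strand labelling.
#
# Strands are maximal runs of residues participating in inter-strand ladders.
# A ladder rung links two residues either by a geometric backbone hydrogen
# bond (backbone mode) or by Ca-Ca proximity (ca_only mode); a ladder needs at
# least `min_ladder_rungs` consecutive rungs. Sheets are connected components
# of the strand-adjacency graph.

# find maximal ladder runs among unordered residue-index pairs.
# pairs: 2-column matrix (i < j). A run may skip over `gap` missing rungs
# (beta-bulge tolerance). Returns list of runs:
# list(i = vector, j = vector, orientation = "parallel"/"antiparallel")
ladder_runs <- function(pairs, min_rungs = 2, gap = 1) {
  if (is.null(pairs) || nrow(pairs) == 0) return(list())
  keys <- paste(pairs[, 1], pairs[, 2])
  has <- function(i, j) paste(i, j) %in% keys
  walk <- function(i, j, dj) {
    is <- integer(0); js <- integer(0)
    skipped <- 0
    while (i < j || dj > 0) {
      if (has(i, j)) { is <- c(is, i); js <- c(js, j); skipped <- 0 }
      else if (skipped < gap && length(is)) skipped <- skipped + 1
      else break
      i <- i + 1; j <- j + dj
      if (dj < 0 && i >= j) break
    }
    list(i = is, j = js)
  }
  runs <- list()
  used <- list(antiparallel = character(0), parallel = character(0))
  ord <- order(pairs[, 1], pairs[, 2])
  for (r in ord) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    for (orientation in c("antiparallel", "parallel")) {
      dj <- if (orientation == "antiparallel") -1L else 1L
      if (paste(i, j) %in% used[[orientation]]) next
      # only start at a run head (no extendable rung one step back)
      if (has(i - 1, j - dj) || (gap >= 1 && has(i - 2, j - 2 * dj))) next
      w <- walk(i, j, dj)
      if (length(w$i) >= min_rungs) {
        runs[[length(runs) + 1]] <- list(i = w$i, j = w$j, orientation = orientation)
        used[[orientation]] <- c(used[[orientation]], paste(w$i, w$j))
      }
    }
  }
  runs
}

# extended-conformation mask: a residue joins a ladder only when the chain is
# locally straight at or next to it (strand residues are extended; loop and
# turn residues are not). Turn angle = angle between consecutive Ca steps.
extended_mask <- function(xyz, turn_max) {
  n <- nrow(xyz)
  steps <- xyz[-1, , drop = FALSE] - xyz[-n, , drop = FALSE]
  steps <- steps / pmax(sqrt(rowSums(steps^2)), 1e-9)
  cosr <- rowSums(steps[-1, , drop = FALSE] * steps[-(n - 1), , drop = FALSE])
  turn <- acos(pmax(-1, pmin(1, cosr))) * 180 / pi   # turn at residues 2..n-1
  small <- c(FALSE, turn <= turn_max, FALSE)
  small | c(small[-1], FALSE) | c(FALSE, small[-n])
}

# beta-ladder geometry: partners run along (anti)parallel local directions and
# the connecting vector is lateral, not along the chain. Each residue offers
# its backward and forward Ca steps; the best-aligned combination is used, so
# strand-end residues (whose outward step runs into a loop) still qualify
# through their inward step.
rung_steps <- function(xyz) {
  n <- nrow(xyz)
  st <- xyz[-1, , drop = FALSE] - xyz[-n, , drop = FALSE]
  st <- st / pmax(sqrt(rowSums(st^2)), 1e-9)
  list(back = rbind(st[1, ], st), fwd = rbind(st, st[n - 1, ]))
}

rung_geometry_ok <- function(xyz, steps, i, j) {
  w <- xyz[j, ] - xyz[i, ]
  w <- w / max(vnorm(w), 1e-9)
  for (u in list(steps$back[i, ], steps$fwd[i, ]))
    for (v in list(steps$back[j, ], steps$fwd[j, ])) {
      if (abs(sum(u * v)) > 0.7 &&
          abs(sum(u * w)) < 0.5 && abs(sum(v * w)) < 0.5) return(TRUE)
    }
  FALSE
}

# candidate rungs between residues of one chain
ca_rung_pairs <- function(xyz, max_dist, min_sep, turn_max = 45) {
  n <- nrow(xyz)
  d2 <- as.matrix(stats::dist(xyz))^2
  sel <- which(upper.tri(d2) & d2 <= max_dist^2, arr.ind = TRUE)
  if (nrow(sel)) sel <- sel[sel[, 2] - sel[, 1] >= min_sep, , drop = FALSE]
  if (nrow(sel)) {
    ext <- extended_mask(xyz, turn_max)
    sel <- sel[ext[sel[, 1]] & ext[sel[, 2]], , drop = FALSE]
  }
  if (nrow(sel)) {
    steps <- rung_steps(xyz)
    ok <- vapply(seq_len(nrow(sel)), function(k)
      rung_geometry_ok(xyz, steps, sel[k, 1], sel[k, 2]), logical(1))
    sel <- sel[ok, , drop = FALSE]
  }
  sel
}

# geometric backbone H-bond rungs: N...O distance and donor angle criterion
hbond_rung_pairs <- function(structure, trace, config) {
  at <- structure$atoms[structure$atoms$chain == trace$chain_id, , drop = FALSE]
  key <- paste(trace$resno, trace$ins, sep = "|")
  akey <- paste(at$resno, at$ins, sep = "|")
  getatom <- function(name) {
    sub <- at[at$elety == name, , drop = FALSE]
    m <- match(key, paste(sub$resno, sub$ins, sep = "|"))
    cbind(sub$x[m], sub$y[m], sub$z[m])
  }
  N <- getatom("N"); O <- getatom("O"); CA <- trace$xyz
  n <- nrow(CA)
  steps <- rung_steps(CA)
  ext <- extended_mask(CA, config$extended_turn_max)
  out <- matrix(integer(0), ncol = 2)
  for (d in seq_len(n)) {
    if (anyNA(N[d, ]) || !ext[d]) next
    dv <- sweep(O, 2, N[d, ])
    dd <- sqrt(rowSums(dv^2))
    cand <- which(dd <= config$hbond_no_dist & abs(seq_len(n) - d) >= config$min_seq_sep)
    for (a in cand) {
      if (anyNA(O[a, ])) next
      # donor angle at N between its Ca and the acceptor O
      u <- CA[d, ] - N[d, ]; w <- O[a, ] - N[d, ]
      ang <- vec_angle(u, w)
      if (ang >= config$hbond_donor_angle && ext[a]) {
        i <- min(d, a); j <- max(d, a)
        if (rung_geometry_ok(CA, steps, i, j)) out <- rbind(out, c(i, j))
      }
    }
  }
  unique(out)
}

segment_strands <- function(in_strand, trace, config) {
  n <- length(in_strand)
  # bulge tolerance: fill isolated interruptions inside ladders
  tol <- config$bulge_tolerance
  if (tol > 0) {
    for (i in seq_len(n)) {
      if (!in_strand[i]) {
        lo <- i - 1; hi <- i + tol
        if (lo >= 1 && hi <= n && in_strand[lo] && all(!in_strand[i:(hi - 1)]) && in_strand[hi])
          in_strand[i:(hi - 1)] <- TRUE
      }
    }
  }
  r <- rle(in_strand)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  segs <- cbind(starts[r$values], ends[r$values])
  # break segments across numbering gaps (missing residues)
  out <- list()
  for (k in seq_len(nrow(segs))) {
    idx <- segs[k, 1]:segs[k, 2]
    brk <- which(diff(trace$resno[idx]) > 2)
    parts <- split(idx, cumsum(seq_along(idx) %in% (brk + 1)))
    for (p in parts) if (length(p) >= config$min_strand_len) out[[length(out) + 1]] <- p
  }
  out
}

components_of <- function(n, edges) {
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (k in seq_len(nrow(edges))) {
      a <- edges[k, 1]; b <- edges[k, 2]
      m <- min(comp[a], comp[b])
      if (comp[a] != m || comp[b] != m) { comp[comp == comp[a] | comp == comp[b]] <- m; changed <- TRUE }
    }
    if (!changed) break
  }
  match(comp, sort(unique(comp)))
}

#' Detect beta-strands and sheets of a chain
#'
#' Finds inter-strand ladders, segments the chain into strands, groups strands
#' into sheets (connected components of lateral adjacency) and records the
#' residue-pair registers of every adjacent strand pair. A strand whose
#' residues ladder to two different sheets is split in two at a hinge residue
#' (first proline, else the midpoint of the longest glycine run between the
#' laddered segments, else the geometric crossover) -- this realizes the A/A'
#' split of variable-type Ig domains.
#'
#' @param structure a `StructureModel`.
#' @param chain_id chain identifier.
#' @param mode `"ca_only"` (Ca-Ca ladder distance criterion) or `"backbone"`
#'   (geometric N...O hydrogen-bond criterion).
#' @param config see [igproto_config()].
#' @return an object of class `SheetModel`: list with
#'   \describe{
#'     \item{strands}{list of strands, each with `index`, `idx` (trace
#'       indices), `resno`, `ins`, `resid`, `sheet_id`, `hinge` (set on split
#'       products).}
#'     \item{sheet_ids}{integer sheet id per strand.}
#'     \item{adjacency}{data.frame s1, s2, n_rungs, orientation.}
#'     \item{registers}{named list ("s1|s2") of paired-residue data.frames.}
#'     \item{trace}{the `CaTrace` used.}
#'     \item{single_sheet}{warning flag: fewer than two sheets found.}
#'   }
#' @export
detect_strands <- function(structure, chain_id, mode = c("ca_only", "backbone"),
                           config = igproto_config()) {
  mode <- match.arg(mode)
  trace <- extract_ca(structure, chain_id)
  n <- nrow(trace$xyz)
  if (n < 20) stop("chain ", chain_id, " has fewer than 20 residues with Ca")
  pairs <- if (mode == "ca_only")
    ca_rung_pairs(trace$xyz, config$ca_ladder_dist, config$min_seq_sep,
                  config$extended_turn_max)
  else hbond_rung_pairs(structure, trace, config)
  runs <- ladder_runs(pairs, config$min_ladder_rungs, config$bulge_tolerance)
  if (!length(runs))
    stop("no beta-strands found in chain ", chain_id,
         " (", nrow(pairs), " candidate rungs, none forming a ladder)")
  in_strand <- rep(FALSE, n)
  for (r in runs) in_strand[c(r$i, r$j)] <- TRUE
  segs <- segment_strands(in_strand, trace, config)
  model <- build_sheet_model(segs, runs, trace, config)
  model <- split_cross_sheet_strands(model, runs, trace, config)
  model$mode <- mode
  model
}

build_sheet_model <- function(segs, runs, trace, config) {
  ns <- length(segs)
  strand_of <- rep(NA_integer_, nrow(trace$xyz))
  for (k in seq_len(ns)) strand_of[segs[[k]]] <- k
  adj <- list(); registers <- list()
  for (r in runs) {
    si <- strand_of[r$i]; sj <- strand_of[r$j]
    ok <- !is.na(si) & !is.na(sj) & si != sj
    if (!any(ok)) next
    for (pair in unique(paste(pmin(si[ok], sj[ok]), pmax(si[ok], sj[ok])))) {
      ab <- as.integer(strsplit(pair, " ")[[1]])
      sel <- ok & pmin(si, sj) == ab[1] & pmax(si, sj) == ab[2]
      reg <- data.frame(
        resno_i = trace$resno[r$i[sel]], ins_i = trace$ins[r$i[sel]],
        resno_j = trace$resno[r$j[sel]], ins_j = trace$ins[r$j[sel]],
        orientation = r$orientation, stringsAsFactors = FALSE)
      key <- paste(ab[1], ab[2], sep = "|")
      registers[[key]] <- if (is.null(registers[[key]])) reg else
        unique(rbind(registers[[key]], reg))
    }
  }
  if (length(registers)) {
    for (key in names(registers)) {
      ab <- as.integer(strsplit(key, "\\|")[[1]])
      reg <- registers[[key]]
      if (nrow(reg) >= config$min_ladder_rungs) {
        orient <- names(which.max(table(reg$orientation)))
        adj[[length(adj) + 1]] <- data.frame(s1 = ab[1], s2 = ab[2],
                                             n_rungs = nrow(reg),
                                             orientation = orient,
                                             stringsAsFactors = FALSE)
      } else registers[[key]] <- NULL
    }
  }
  adj <- if (length(adj)) do.call(rbind, adj) else
    data.frame(s1 = integer(0), s2 = integer(0), n_rungs = integer(0),
               orientation = character(0))
  sheet_ids <- components_of(ns, as.matrix(adj[, c("s1", "s2"), drop = FALSE]))
  strands <- lapply(seq_len(ns), function(k) {
    idx <- segs[[k]]
    list(index = k, idx = idx, resno = trace$resno[idx], ins = trace$ins[idx],
         resid = trace$resid[idx], sheet_id = sheet_ids[k], hinge = NULL,
         label = NA_character_)
  })
  structure(list(strands = strands, sheet_ids = sheet_ids, adjacency = adj,
                 registers = registers, trace = trace,
                 single_sheet = length(unique(sheet_ids[sapply(strands, function(s)
                   length(s$idx)) > 0])) < 2),
            class = "SheetModel")
}

# Split strands whose residues ladder to two different sheets (A/A' split).
# A candidate strand may itself be the only bridge between the two sheets, so
# its partners are grouped by the connected components of the adjacency graph
# with the candidate removed.
split_cross_sheet_strands <- function(model, runs, trace, config) {
  ns <- length(model$strands)
  strand_of <- rep(NA_integer_, nrow(trace$xyz))
  for (s in model$strands) strand_of[s$idx] <- s$index
  segs <- lapply(model$strands, function(s) s$idx)
  changed <- FALSE
  adj <- as.matrix(model$adjacency[, c("s1", "s2"), drop = FALSE])
  for (k in seq_len(ns)) {
    s <- model$strands[[k]]
    # partner strand of each residue of s
    partner_at <- lapply(seq_along(s$idx), function(z) integer(0))
    for (r in runs) {
      for (side in 1:2) {
        a <- if (side == 1) r$i else r$j
        b <- if (side == 1) r$j else r$i
        hit <- which(a %in% s$idx)
        for (h in hit) {
          ps <- strand_of[b[h]]
          if (!is.na(ps) && ps != k) {
            z <- match(a[h], s$idx)
            partner_at[[z]] <- c(partner_at[[z]], ps)
          }
        }
      }
    }
    # component of each partner in the graph without strand k
    sub <- adj[adj[, 1] != k & adj[, 2] != k, , drop = FALSE]
    comp <- components_of(ns, sub)
    comp_at <- lapply(partner_at, function(p) unique(comp[p]))
    comps_hit <- sort(unique(unlist(comp_at)))
    pos_by_comp <- lapply(comps_hit, function(cc)
      which(vapply(comp_at, function(p) cc %in% p, logical(1))))
    nhits <- vapply(pos_by_comp, length, integer(1))
    big <- which(nhits >= config$min_ladder_rungs)
    if (length(big) < 2) next
    big <- big[order(nhits[big], decreasing = TRUE)][1:2]
    b1 <- pos_by_comp[[big[1]]]; b2 <- pos_by_comp[[big[2]]]
    if (max(b1) < min(b2)) { lo <- max(b1); hi <- min(b2) }
    else if (max(b2) < min(b1)) { lo <- max(b2); hi <- min(b1) }
    else next   # interleaved: not separable
    hinge_z <- pick_hinge(s, lo, hi)
    i1 <- s$idx[seq_len(max(1, hinge_z - 1))]
    i2 <- s$idx[seq(min(length(s$idx), hinge_z + 1), length(s$idx))]
    if (length(i1) >= config$min_strand_len && length(i2) >= config$min_strand_len) {
      segs[[k]] <- i1
      segs[[length(segs) + 1]] <- i2
      attr(segs, "hinge") <- c(attr(segs, "hinge"), trace$resno[s$idx[hinge_z]])
      changed <- TRUE
    }
  }
  if (!changed) return(model)
  hinges <- attr(segs, "hinge")
  segs <- segs[order(vapply(segs, min, integer(1)))]
  model2 <- build_sheet_model(segs, runs, trace, config)
  model2$hinges <- hinges
  model2
}

# hinge between positions lo and hi (indices into s$idx): first proline, else
# midpoint of the longest glycine run, else geometric midpoint
pick_hinge <- function(s, lo, hi) {
  if (hi <= lo + 1) return(floor((lo + hi) / 2))
  zz <- (lo + 1):(hi - 1)
  res <- s$resid[zz]
  p <- which(res == "PRO")
  if (length(p)) return(zz[p[1]])
  g <- rle(res == "GLY")
  if (any(g$values)) {
    ends <- cumsum(g$lengths)
    gi <- which(g$values)
    gi <- gi[which.max(g$lengths[gi])]
    return(zz[ends[gi] - floor((g$lengths[gi] - 1) / 2) - ifelse(g$lengths[gi] > 1, 0, 0)])
  }
  zz[ceiling(length(zz) / 2)]
}

#' @export
print.SheetModel <- function(x, ...) {
  cat("SheetModel:", length(x$strands), "strands in",
      length(unique(x$sheet_ids)), "sheet(s)\n")
  invisible(x)
}

.side_A_labels <- c("A", "B", "E", "D")
.side_B_labels <- c("A'", "G", "F", "C", "C'", "C''")

#' Assign canonical Ig strand labels
#'
#' Labels detected strands with the canonical Ig nomenclature (A, A', B, C,
#' C', C'', D, E, F, G). The invariant core is anchored first: the four
#' strands B, C, E, F are the longest quadruple (in N-to-C order) in which B
#' and E ladder laterally in one sheet, C and F in the other -- the
#' intertwined BC/EF straddle common to all Ig and Ig-like domains. Remaining
#' labels follow from sequence position and sheet membership: strands
#' preceding B become A (on the B-side sheet) and/or A' (on the C-side sheet);
#' strands between C and E become C' and C'' (C-side) or D (B-side); the first
#' strand after F on the C-side sheet becomes G. A manual override wins over
#' detection after validation.
#'
#' @param det a `SheetModel` from [detect_strands()].
#' @param override optional named list: label -> `c(start, end)` residue
#'   interval in source numbering.
#' @param config see [igproto_config()].
#' @return an object of class `IgAnnotation`; when the core straddle cannot be
#'   identified, a typed not-Ig-like verdict (`is_ig = FALSE` with `reason`)
#'   rather than an error. Fields: `strands` (labelled), `sheet_A`, `sheet_B`
#'   (label sets), `loops` (CDR1/CDR2/CDR3/HV2/HV4 residue intervals),
#'   `a_split`, `hinge`, `det` (the detection result), `chain_id`.
#' @export
label_ig_strands <- function(det, override = NULL, config = igproto_config()) {
  stopifnot(inherits(det, "SheetModel"))
  if (!is.null(override)) return(annotation_from_override(det, override))
  strands <- det$strands
  ns <- length(strands)
  not_ig <- function(reason)
    structure(list(is_ig = FALSE, reason = reason, strands = strands,
                   det = det, chain_id = det$trace$chain_id),
              class = "IgAnnotation")
  # restrict to the two most populated sheets
  tab <- sort(table(det$sheet_ids), decreasing = TRUE)
  if (length(tab) < 2) return(not_ig("fewer than two beta-sheets detected"))
  main <- as.integer(names(tab)[1:2])
  cand <- which(det$sheet_ids %in% main)
  if (length(cand) < 4) return(not_ig("fewer than four strands across the two sheets"))
  adjacent <- function(a, b) any((det$adjacency$s1 == a & det$adjacency$s2 == b) |
                                 (det$adjacency$s1 == b & det$adjacency$s2 == a))
  slen <- vapply(strands, function(s) length(s$idx), integer(1))
  best <- NULL; best_len <- -1
  for (b in cand) for (c in cand) for (e in cand) for (f in cand) {
    if (!(b < c && c < e && e < f)) next
    if (det$sheet_ids[b] != det$sheet_ids[e]) next
    if (det$sheet_ids[c] != det$sheet_ids[f]) next
    if (det$sheet_ids[b] == det$sheet_ids[c]) next
    if (!adjacent(b, e) || !adjacent(c, f)) next
    tot <- slen[b] + slen[c] + slen[e] + slen[f]
    if (tot > best_len) { best_len <- tot; best <- c(b, c, e, f) }
  }
  if (is.null(best))
    return(not_ig("core BC/EF straddle not identifiable"))
  lab <- rep(NA_character_, ns)
  lab[best] <- c("B", "C", "E", "F")
  sheetA <- det$sheet_ids[best[1]]   # sheet of B (the ABED side)
  sheetB <- det$sheet_ids[best[2]]   # sheet of C (the A'GFCC'C'' side)
  pre <- cand[cand < best[1]]
  for (k in pre) {
    if (det$sheet_ids[k] == sheetA && !"A" %in% lab) lab[k] <- "A"
    else if (det$sheet_ids[k] == sheetB && !"A'" %in% lab) lab[k] <- "A'"
  }
  mid <- cand[cand > best[2] & cand < best[3]]
  for (k in mid) {
    if (det$sheet_ids[k] == sheetB) {
      if (!"C'" %in% lab) lab[k] <- "C'"
      else if (!"C''" %in% lab) lab[k] <- "C''"
    } else if (!"D" %in% lab) lab[k] <- "D"
  }
  post <- cand[cand > best[4]]
  for (k in post) if (det$sheet_ids[k] == sheetB && !"G" %in% lab) lab[k] <- "G"
  for (k in seq_len(ns)) strands[[k]]$label <- lab[k]
  # Rescue pass for very short lateral strands that the extended-conformation
  # gate can miss: when the surrounding labels imply one (a split A/A'
  # context), the unassigned residues between the flanking strands are
  # scanned for a plain lateral ladder to the anchor strand.
  rescue <- function(anchor_lab, window, new_label, sheet_id) {
    if (!anchor_lab %in% lab || length(window) < config$min_ladder_rungs) return(NULL)
    anchor <- strands[[which(lab == anchor_lab)[1]]]
    used <- unlist(lapply(strands, `[[`, "idx"))
    window <- setdiff(window, used)
    if (length(window) < config$min_ladder_rungs) return(NULL)
    trace <- det$trace
    steps <- rung_steps(trace$xyz)
    # slightly looser distance than strict detection and a one-residue gap:
    # the context (labels flanking the window) already implies the strand
    ok <- vapply(window, function(i) any(vapply(anchor$idx, function(j) {
      abs(i - j) >= config$min_seq_sep &&
        vnorm(trace$xyz[i, ] - trace$xyz[j, ]) <= config$ca_ladder_dist + 0.5 &&
        rung_geometry_ok(trace$xyz, steps, min(i, j), max(i, j))
    }, logical(1))), logical(1))
    if (sum(ok) < config$min_ladder_rungs) return(NULL)
    span <- range(which(ok))
    inner <- ok[span[1]:span[2]]
    if (any(!inner)) {
      r <- rle(inner)
      if (max(r$lengths[!r$values]) > config$bulge_tolerance) {
        # fall back to the longest clean stretch
        ends <- cumsum(r$lengths)
        runs <- which(r$values & r$lengths >= config$min_ladder_rungs)
        if (!length(runs)) return(NULL)
        b <- runs[which.max(r$lengths[runs])]
        span <- span[1] - 1 + c(ends[b] - r$lengths[b] + 1, ends[b])
      }
    }
    idx <- window[span[1]:span[2]]
    if (!all(diff(idx) == 1)) return(NULL)
    list(index = length(strands) + 1L, idx = idx, resno = trace$resno[idx],
         ins = trace$ins[idx], resid = trace$resid[idx], sheet_id = sheet_id,
         hinge = NULL, label = new_label)
  }
  add_rescued <- function(st) {
    if (is.null(st)) return(invisible(NULL))
    strands[[st$index]] <<- st
    lab[st$index] <<- st$label
    det$sheet_ids <<- c(det$sheet_ids, st$sheet_id)
  }
  if (!"A'" %in% lab && "A" %in% lab && "G" %in% lab) {
    ia <- which(lab == "A")
    w <- (max(strands[[ia]]$idx) + 1):(min(strands[[best[1]]]$idx) - 1)
    add_rescued(rescue("G", w, "A'", sheetB))
  }
  if (!"A" %in% lab && "A'" %in% lab && min(strands[[which(lab == "A'")]]$idx) > 2) {
    w <- 1:(min(strands[[which(lab == "A'")]]$idx) - 1)
    add_rescued(rescue("B", w, "A", sheetA))
  }
  if (!"C'" %in% lab && "A" %in% lab && "A'" %in% lab) {
    after_c <- cand[cand > best[2]]
    nxt <- if (length(after_c)) min(vapply(after_c, function(k)
      min(strands[[k]]$idx), integer(1))) else nrow(det$trace$xyz) + 1
    w <- (max(strands[[best[2]]]$idx) + 1):(nxt - 1)
    add_rescued(rescue("C", w, "C'", sheetB))
  }
  ns <- length(strands)
  a_split <- "A" %in% lab && "A'" %in% lab
  hinge <- if (a_split && length(det$hinges)) det$hinges[1] else
    if (a_split) {
      ia <- which(lab == "A"); ip <- which(lab == "A'")
      gapmid(strands[[ia]], strands[[ip]], det$trace)
    } else NULL
  loops <- list(
    CDR1 = loop_interval(strands, lab, "B", "C", det$trace),
    CDR2 = loop_interval(strands, lab, "C'", "C''", det$trace),
    CDR3 = loop_interval(strands, lab, "F", "G", det$trace),
    HV2  = if (!"C''" %in% lab) loop_interval(strands, lab, "C'", "D", det$trace) else NULL,
    HV4  = loop_interval(strands, lab, "D", "E", det$trace)
  )
  structure(list(
    is_ig = TRUE, reason = NULL, strands = strands,
    sheet_A = lab[!is.na(lab) & det$sheet_ids == sheetA],
    sheet_B = lab[!is.na(lab) & det$sheet_ids == sheetB],
    a_split = a_split, hinge = hinge, loops = loops,
    det = det, chain_id = det$trace$chain_id
  ), class = "IgAnnotation")
}

loop_interval <- function(strands, lab, from, to, trace) {
  i <- which(lab == from); j <- which(lab == to)
  if (!length(i) || !length(j)) return(NULL)
  a <- max(strands[[i]]$idx); b <- min(strands[[j]]$idx)
  if (b - a < 2) return(NULL)
  c(trace$resno[a + 1], trace$resno[b - 1])
}

gapmid <- function(s1, s2, trace) {
  a <- max(s1$idx); b <- min(s2$idx)
  trace$resno[floor((a + b) / 2)]
}

annotation_from_override <- function(det, override) {
  valid <- c("A", "A'", "B", "C", "C'", "C''", "D", "E", "F", "G")
  bad <- setdiff(names(override), valid)
  if (length(bad)) stop("override validation failed, unknown label(s): ",
                        paste(bad, collapse = ", "))
  if (anyDuplicated(names(override)))
    stop("override validation failed, duplicated label(s): ",
         paste(unique(names(override)[duplicated(names(override))]), collapse = ", "))
  trace <- det$trace
  strands <- list(); k <- 0
  ord <- order(vapply(override, function(r) r[1], numeric(1)))
  override <- override[ord]
  conflicts <- character(0)
  taken <- rep(FALSE, nrow(trace$xyz))
  for (nm in names(override)) {
    rng <- override[[nm]]
    idx <- which(trace$resno >= rng[1] & trace$resno <= rng[2])
    if (!length(idx)) { conflicts <- c(conflicts, paste0(nm, ": empty interval")); next }
    if (any(taken[idx])) conflicts <- c(conflicts, paste0(nm, ": overlaps another strand"))
    taken[idx] <- TRUE
    k <- k + 1
    strands[[k]] <- list(index = k, idx = idx, resno = trace$resno[idx],
                         ins = trace$ins[idx], resid = trace$resid[idx],
                         sheet_id = if (nm %in% .side_A_labels) 1L else 2L,
                         hinge = NULL, label = nm)
  }
  if (length(conflicts))
    stop("override validation failed: ", paste(conflicts, collapse = "; "))
  lab <- vapply(strands, function(s) s$label, character(1))
  core <- all(c("B", "C", "E", "F") %in% lab)
  structure(list(
    is_ig = core, reason = if (!core) "override lacks the BCEF core" else NULL,
    strands = strands,
    sheet_A = intersect(lab, .side_A_labels),
    sheet_B = intersect(lab, .side_B_labels),
    a_split = all(c("A", "A'") %in% lab), hinge = NULL,
    loops = list(CDR1 = loop_interval(strands, lab, "B", "C", trace),
                 CDR2 = loop_interval(strands, lab, "C'", "C''", trace),
                 CDR3 = loop_interval(strands, lab, "F", "G", trace),
                 HV2 = NULL, HV4 = loop_interval(strands, lab, "D", "E", trace)),
    det = det, chain_id = trace$chain_id
  ), class = "IgAnnotation")
}

#' @export
print.IgAnnotation <- function(x, ...) {
  if (!isTRUE(x$is_ig)) {
    cat("IgAnnotation: not Ig-like (", x$reason, ")\n", sep = ""); return(invisible(x))
  }
  cat("IgAnnotation chain ", x$chain_id, ": sheet A [",
      paste(x$sheet_A, collapse = " "), "], sheet B [",
      paste(x$sheet_B, collapse = " "), "]",
      if (x$a_split) ", split A/A'" else "", "\n", sep = "")
  invisible(x)
}

annotation_strand <- function(annotation, label) {
  for (s in annotation$strands) if (identical(s$label, label)) return(s)
  NULL
}

annotation_labels <- function(annotation)
  vapply(annotation$strands, function(s) if (is.na(s$label)) "" else s$label, character(1))
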