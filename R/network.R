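# Typed residue-interaction networks at protodomain cores and quaternary
# interfaces. All criteria are geometric (no hydrogen placement, no energies);
# thresholds follow common interactive-viewer defaults and are configurable.

.donor_atoms <- list(
  ALL = "N",
  ARG = c("NE", "NH1", "NH2"), LYS = "NZ", HIS = c("ND1", "NE2"),
  ASN = "ND2", GLN = "NE2", SER = "OG", THR = "OG1", TYR = "OH", TRP = "NE1")
.acceptor_atoms <- list(
  ALL = c("O", "OXT"),
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = "OD1", GLN = "OE1",
  SER = "OG", THR = "OG1", TYR = "OH", HIS = c("ND1", "NE2"), MET = "SD")
.anionic_atoms <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
.cationic_atoms <- list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"),
                        HIS = c("ND1", "NE2"))
.ring_atoms <- list(
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2"))

res_atom_set <- function(at, table, resid) {
  names <- c(table$ALL, table[[resid]])
  at[at$elety %in% names, , drop = FALSE]
}

#' Classify the interaction between two residues
#'
#' Fires every geometric criterion independently; a residue pair can carry
#' several interaction types at once. Criteria (all thresholds in
#' [igproto_config()]): van der Waals contact, any heavy-atom pair within
#' `vdw_dist`; hydrogen bond, donor-heavy to acceptor-heavy atom within
#' `hbond_dist` with the donor angle (antecedent-donor-acceptor) at least
#' `hbond_angle`; ionic, Asp/Glu carboxylate to Lys/Arg/His nitrogen within
#' `ionic_dist`; pi stacking, aromatic ring centroids within `pi_stack_dist`;
#' pi-cation, ring centroid to cationic nitrogen within `pi_cation_dist`;
#' disulfide, SG-SG within `disulfide_dist`.
#'
#' @param structure a `StructureModel`.
#' @param res_i,res_j residue references: `list(chain, resno, ins = "")`.
#' @param config see [igproto_config()].
#' @return an `InteractionEdge` (list with `residues`, `types`,
#'   `min_distance`, `partial`) or `NULL` when no criterion fires or the
#'   residues are sequence-adjacent on the same chain.
#' @export
classify_contact <- function(structure, res_i, res_j, config = igproto_config()) {
  get <- function(r) {
    ins <- if (is.null(r$ins)) "" else r$ins
    at <- structure$atoms
    at[at$chain == r$chain & at$resno == r$resno & at$ins == ins, , drop = FALSE]
  }
  A <- get(res_i); B <- get(res_j)
  if (nrow(A) == 0 || nrow(B) == 0) stop("residue not found in structure")
  if (identical(res_i$chain, res_j$chain)) {
    if (res_i$resno == res_j$resno &&
        identical(res_i$ins %||% "", res_j$ins %||% ""))
      stop("classify_contact needs two distinct residues")
    if (abs(res_i$resno - res_j$resno) < 2) return(NULL)
  }
  D <- cross_min_dist(A, B)
  dmin <- min(D)
  types <- character(0)
  if (dmin <= config$vdw_dist) types <- c(types, "vdw")
  ra <- A$resid[1]; rb <- B$resid[1]
  # hydrogen bond, both donor->acceptor directions
  hb <- function(don, donres, acc, accres) {
    d_at <- res_atom_set(don, .donor_atoms, donres)
    a_at <- res_atom_set(acc, .acceptor_atoms, accres)
    if (nrow(d_at) == 0 || nrow(a_at) == 0) return(FALSE)
    for (di in seq_len(nrow(d_at))) {
      dpos <- as.numeric(d_at[di, c("x", "y", "z")])
      others <- don[!(don$elety == d_at$elety[di]), , drop = FALSE]
      if (nrow(others) == 0) next
      od <- cross_min_dist(d_at[di, , drop = FALSE], others)
      ante <- as.numeric(others[which.min(od), c("x", "y", "z")])
      for (ai in seq_len(nrow(a_at))) {
        apos <- as.numeric(a_at[ai, c("x", "y", "z")])
        if (vnorm(apos - dpos) <= config$hbond_dist &&
            vec_angle(ante - dpos, apos - dpos) >= config$hbond_angle)
          return(TRUE)
      }
    }
    FALSE
  }
  if (hb(A, ra, B, rb) || hb(B, rb, A, ra)) types <- c(types, "hbond")
  ion <- function(an, anres, cat, catres) {
    x <- res_atom_set(an, .anionic_atoms, anres)
    y <- res_atom_set(cat, .cationic_atoms, catres)
    nrow(x) > 0 && nrow(y) > 0 && min(cross_min_dist(x, y)) <= config$ionic_dist
  }
  if (ion(A, ra, B, rb) || ion(B, rb, A, ra)) types <- c(types, "ionic")
  centroid <- function(at, resid) {
    ring <- .ring_atoms[[resid]]
    if (is.null(ring)) return(NULL)
    r <- at[at$elety %in% ring, , drop = FALSE]
    if (nrow(r) < 3) return(NULL)
    colMeans(as.matrix(r[, c("x", "y", "z")]))
  }
  cA <- centroid(A, ra); cB <- centroid(B, rb)
  if (!is.null(cA) && !is.null(cB) && vnorm(cA - cB) <= config$pi_stack_dist)
    types <- c(types, "pi_stack")
  pc <- function(cen, other, otherres) {
    if (is.null(cen)) return(FALSE)
    y <- res_atom_set(other, .cationic_atoms, otherres)
    nrow(y) > 0 && min(cross_min_dist(
      data.frame(x = cen[1], y = cen[2], z = cen[3]), y)) <= config$pi_cation_dist
  }
  if (pc(cA, B, rb) || pc(cB, A, ra)) types <- c(types, "pi_cation")
  if (ra == "CYS" && rb == "CYS") {
    sa <- A[A$elety == "SG", , drop = FALSE]; sb <- B[B$elety == "SG", , drop = FALSE]
    if (nrow(sa) && nrow(sb) && min(cross_min_dist(sa, sb)) <= config$disulfide_dist)
      types <- c(types, "disulfide")
  }
  if (!length(types)) return(NULL)
  backbone <- c("N", "CA", "C", "O", "CB", "OXT")
  partial <- (!ra %in% c("GLY", "ALA") && all(A$elety %in% backbone)) ||
             (!rb %in% c("GLY", "ALA") && all(B$elety %in% backbone))
  structure(list(
    residues = list(i = list(chain = res_i$chain, key = rkey(res_i$resno, res_i$ins %||% ""), name = ra),
                    j = list(chain = res_j$chain, key = rkey(res_j$resno, res_j$ins %||% ""), name = rb)),
    types = types, min_distance = dmin, partial = partial
  ), class = "InteractionEdge")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

new_network <- function(nodes, edges, interface_name) {
  structure(list(nodes = nodes, edges = edges, interface_name = interface_name),
            class = "InteractionNetwork")
}

#' @export
print.InteractionNetwork <- function(x, ...) {
  cat("InteractionNetwork '", x$interface_name, "': ", nrow(x$nodes),
      " nodes, ", length(x$edges), " edges\n", sep = "")
  invisible(x)
}

network_edges <- function(structure, resA, resB, same_chain_pairs, config) {
  edges <- list()
  # candidate pre-filter on Ca distance keeps the pair count manageable
  for (k in seq_len(nrow(resA))) for (l in seq_len(nrow(resB))) {
    if (same_chain_pairs && resA$chain[k] == resB$chain[l] &&
        resA$resno[k] >= resB$resno[l]) next
    e <- classify_contact(structure,
                          list(chain = resA$chain[k], resno = resA$resno[k], ins = resA$ins[k]),
                          list(chain = resB$chain[l], resno = resB$resno[l], ins = resB$ins[l]),
                          config)
    if (!is.null(e)) edges[[length(edges) + 1]] <- e
  }
  edges
}

#' Residue-interaction network of the protodomain core interface
#'
#' Builds the typed network over the residues of the four central strands B,
#' C, E, F (optionally including the BC and EF loop residues). Each edge is
#' annotated as lateral (B|E or C|F: the in-sheet ladder interactions),
#' cross-sheet (B-F or C-E: the packing contacts across the sandwich), intra
#' (same strand) or other.
#'
#' @param structure a `StructureModel`.
#' @param annotation an `IgAnnotation` with B, C, E, F labelled.
#' @param include_loops logical, include BC (CDR1) and EF loop residues.
#' @param config see [igproto_config()].
#' @return an `InteractionNetwork`; nodes carry their strand label, edges an
#'   `edge_class` attribute.
#' @export
core_network <- function(structure, annotation, include_loops = FALSE,
                         config = igproto_config()) {
  stopifnot(inherits(annotation, "IgAnnotation"), isTRUE(annotation$is_ig))
  trace <- annotation$det$trace
  rows <- list()
  for (l in c("B", "C", "E", "F")) {
    s <- annotation_strand(annotation, l)
    if (is.null(s)) stop("core_network needs strand ", l, " labelled")
    rows[[l]] <- data.frame(chain = annotation$chain_id, resno = s$resno,
                            ins = s$ins, resid = s$resid, strand = l,
                            stringsAsFactors = FALSE)
  }
  if (include_loops) {
    for (nm in c("CDR1", "EF")) {
      iv <- if (nm == "CDR1") annotation$loops$CDR1 else {
        e <- annotation_strand(annotation, "E"); f <- annotation_strand(annotation, "F")
        a <- max(e$idx); b <- min(f$idx)
        if (b - a >= 2) c(trace$resno[a + 1], trace$resno[b - 1]) else NULL
      }
      if (is.null(iv)) next
      sel <- which(trace$resno >= iv[1] & trace$resno <= iv[2])
      rows[[nm]] <- data.frame(chain = annotation$chain_id, resno = trace$resno[sel],
                               ins = trace$ins[sel], resid = trace$resid[sel],
                               strand = paste0(nm, "_loop"), stringsAsFactors = FALSE)
    }
  }
  nodes <- do.call(rbind, rows); rownames(nodes) <- NULL
  edges <- network_edges(structure, nodes, nodes, same_chain_pairs = TRUE, config)
  smap <- stats::setNames(nodes$strand, rkey(nodes$resno, nodes$ins))
  lateral <- list(c("B", "E"), c("C", "F"))
  cross <- list(c("B", "F"), c("C", "E"))
  for (k in seq_along(edges)) {
    sl <- sort(c(smap[edges[[k]]$residues$i$key], smap[edges[[k]]$residues$j$key]))
    edges[[k]]$edge_class <-
      if (sl[1] == sl[2]) "intra"
      else if (any(vapply(lateral, function(p) all(sort(p) == sl), logical(1)))) "lateral"
      else if (any(vapply(cross, function(p) all(sort(p) == sl), logical(1)))) "cross_sheet"
      else "other"
  }
  nodes$key <- rkey(nodes$resno, nodes$ins)
  new_network(nodes, edges, "BC/EF core")
}

#' Residue-interaction network of a quaternary dimer interface
#'
#' Typed cross-partner contacts between two domains (candidate residues are
#' pre-filtered by an interface scan at the loosest interaction cutoff).
#'
#' @param structure a `StructureModel`.
#' @param domA,domB `IgDomain` references.
#' @param config see [igproto_config()].
#' @return an `InteractionNetwork` over the interface residues; nodes carry
#'   strand labels from their own domain's annotation.
#' @export
dimer_network <- function(structure, domA, domB, config = igproto_config()) {
  loosest <- max(config$vdw_dist, config$hbond_dist, config$ionic_dist,
                 config$pi_stack_dist, config$pi_cation_dist)
  iface <- find_interface(structure, domA, domB, cutoff = loosest, config = config)
  if (iface$empty) return(new_network(
    data.frame(chain = character(0), key = character(0)), list(), "quaternary"))
  mk_nodes <- function(df, dom) {
    smap <- residue_strand_map(dom)
    resno <- as.integer(sub("[A-Za-z]*$", "", df$key))
    ins <- sub("^[0-9]*", "", df$key)
    data.frame(chain = df$chain, resno = resno, ins = ins, resid = df$resid,
               strand = unname(smap[df$key]), key = df$key, stringsAsFactors = FALSE)
  }
  nA <- mk_nodes(iface$contact_residues$A, domA)
  nB <- mk_nodes(iface$contact_residues$B, domB)
  edges <- network_edges(structure, nA, nB, same_chain_pairs = FALSE, config)
  nodes <- rbind(nA, nB); rownames(nodes) <- NULL
  # drop nodes that carry no edge
  used <- unique(unlist(lapply(edges, function(e)
    c(paste(e$residues$i$chain, e$residues$i$key),
      paste(e$residues$j$chain, e$residues$j$key)))))
  nodes <- nodes[paste(nodes$chain, nodes$key) %in% used, , drop = FALSE]
  new_network(nodes, edges, "quaternary")
}

edge_id <- function(e) {
  a <- paste(e$residues$i$chain, e$residues$i$key)
  b <- paste(e$residues$j$chain, e$residues$j$key)
  paste(sort(c(a, b)), collapse = " -- ")
}

#' Compare two interaction networks under a residue mapping
#'
#' An edge of `net1` is conserved iff both mapped endpoints exist in `net2`
#' and the corresponding edge shares at least one interaction type; a node is
#' conserved iff the mapped residue has the same amino-acid identity
#' (conservation is structural-position-based, via the supplied mapping).
#'
#' @param net1,net2 `InteractionNetwork`s.
#' @param mapping a `ResidueCorrespondence`, or a data.frame with columns
#'   `chain_i`, `key_i`, `chain_j`, `key_j` mapping net1 residues to net2
#'   residues. Must cover at least half of each network's nodes.
#' @return list with `conserved_edge_fraction`, `n_edges` (net1), `edges`
#'   (per-edge status), `node_status`, `type_counts` (conserved/total per
#'   interaction type).
#' @export
compare_networks <- function(net1, net2, mapping) {
  if (inherits(mapping, "ResidueCorrespondence"))
    mapping <- data.frame(chain_i = mapping$chain_i, key_i = mapping$pairs$key_i,
                          chain_j = mapping$chain_j, key_j = mapping$pairs$key_j,
                          stringsAsFactors = FALSE)
  if (is.null(mapping) || nrow(mapping) == 0) stop("empty residue mapping")
  id1 <- paste(net1$nodes$chain, net1$nodes$key)
  id2 <- paste(net2$nodes$chain, net2$nodes$key)
  m_from <- paste(mapping$chain_i, mapping$key_i)
  m_to <- paste(mapping$chain_j, mapping$key_j)
  cov1 <- mean(id1 %in% m_from); cov2 <- mean(id2 %in% m_to)
  if (length(id1) && length(id2) && (cov1 < 0.5 || cov2 < 0.5))
    stop(sprintf("mapping covers only %.0f%% / %.0f%% of the networks (need >= 50%%)",
                 100 * cov1, 100 * cov2))
  map <- stats::setNames(m_to, m_from)
  e2 <- lapply(net2$edges, function(e) list(id = edge_id(e), types = e$types))
  e2id <- vapply(e2, `[[`, character(1), "id")
  status <- logical(length(net1$edges))
  type_tot <- list(); type_con <- list()
  for (k in seq_along(net1$edges)) {
    e <- net1$edges[[k]]
    a <- paste(e$residues$i$chain, e$residues$i$key)
    b <- paste(e$residues$j$chain, e$residues$j$key)
    conserved <- FALSE
    if (a %in% names(map) && b %in% names(map)) {
      tid <- paste(sort(c(map[[a]], map[[b]])), collapse = " -- ")
      hit <- which(e2id == tid)
      conserved <- length(hit) > 0 &&
        length(intersect(e$types, e2[[hit[1]]]$types)) > 0
    }
    status[k] <- conserved
    for (ty in e$types) {
      type_tot[[ty]] <- (type_tot[[ty]] %||% 0) + 1
      if (conserved) type_con[[ty]] <- (type_con[[ty]] %||% 0) + 1
    }
  }
  nmap <- stats::setNames(net2$nodes$resid, id2)
  node_status <- data.frame(
    id = id1, resid = net1$nodes$resid,
    mapped = id1 %in% names(map),
    conserved = vapply(seq_along(id1), function(k) {
      if (!id1[k] %in% names(map)) return(FALSE)
      t <- map[[id1[k]]]
      t %in% id2 && identical(nmap[[t]], net1$nodes$resid[k])
    }, logical(1)), stringsAsFactors = FALSE)
  list(conserved_edge_fraction = if (length(status)) mean(status) else NA_real_,
       n_edges = length(status),
       edges = status,
       node_status = node_status,
       type_counts = lapply(stats::setNames(names(type_tot), names(type_tot)),
                            function(ty) c(conserved = type_con[[ty]] %||% 0,
                                           total = type_tot[[ty]])))
}
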