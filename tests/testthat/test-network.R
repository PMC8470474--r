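# small constructed-coordinate structures for contact typing
atoms_row <- function(chain, resno, resid, elety, x, y = 0, z = 0)
  data.frame(chain = chain, resno = resno, ins = "", resid = resid,
             elety = elety, elesy = substr(elety, 1, 1), x = x, y = y, z = z,
             stringsAsFactors = FALSE)

test_that("two alanines with Cb at 3.5 A are a van der Waals contact only", {
  st <- new_structure(rbind(
    atoms_row("A", 1, "ALA", "N", -1.5), atoms_row("A", 1, "ALA", "CA", 0),
    atoms_row("A", 1, "ALA", "O", 0.6), atoms_row("A", 1, "ALA", "CB", 1.0),
    atoms_row("A", 5, "ALA", "CB", 4.5), atoms_row("A", 5, "ALA", "CA", 5.5),
    atoms_row("A", 5, "ALA", "N", 6.1), atoms_row("A", 5, "ALA", "O", 7.0)))
  e <- classify_contact(st, list(chain = "A", resno = 1),
                        list(chain = "A", resno = 5))
  expect_equal(e$types, "vdw")
  expect_equal(e$min_distance, 3.5)
})

test_that("an Asp-Lys salt bridge at 3.0 A fires vdw, ionic and hbond together", {
  st <- new_structure(rbind(
    atoms_row("A", 1, "ASP", "CA", -3), atoms_row("A", 1, "ASP", "CG", -1.3),
    atoms_row("A", 1, "ASP", "OD1", 0), atoms_row("A", 1, "ASP", "OD2", -0.5, 1.2),
    atoms_row("A", 9, "LYS", "NZ", 3.0), atoms_row("A", 9, "LYS", "CE", 4.4),
    atoms_row("A", 9, "LYS", "CA", 7.0)))
  e <- classify_contact(st, list(chain = "A", resno = 1),
                        list(chain = "A", resno = 9))
  expect_setequal(e$types, c("vdw", "ionic", "hbond"))
})

test_that("disulfide, pi-stacking and pi-cation criteria fire on constructed pairs", {
  ss <- new_structure(rbind(
    atoms_row("A", 1, "CYS", "CA", -2), atoms_row("A", 1, "CYS", "SG", 0),
    atoms_row("A", 4, "CYS", "SG", 2.0), atoms_row("A", 4, "CYS", "CA", 4)))
  expect_true("disulfide" %in% classify_contact(
    ss, list(chain = "A", resno = 1), list(chain = "A", resno = 4))$types)
  ring <- function(resno, x0, z = 0) rbind(
    atoms_row("A", resno, "PHE", "CA", x0 - 2, 0, z),
    atoms_row("A", resno, "PHE", "CG", x0 + 0, 0.0, z),
    atoms_row("A", resno, "PHE", "CD1", x0 + 0.7, 1.2, z),
    atoms_row("A", resno, "PHE", "CD2", x0 + 0.7, -1.2, z),
    atoms_row("A", resno, "PHE", "CE1", x0 + 2.1, 1.2, z),
    atoms_row("A", resno, "PHE", "CE2", x0 + 2.1, -1.2, z),
    atoms_row("A", resno, "PHE", "CZ", x0 + 2.8, 0, z))
  pp <- new_structure(rbind(ring(1, 0), ring(5, 0, z = 4.0)))
  expect_true("pi_stack" %in% classify_contact(
    pp, list(chain = "A", resno = 1), list(chain = "A", resno = 5))$types)
  pc <- new_structure(rbind(ring(1, 0),
    atoms_row("A", 6, "LYS", "NZ", 1.4, 0, 4.5),
    atoms_row("A", 6, "LYS", "CA", 3, 0, 7)))
  expect_true("pi_cation" %in% classify_contact(
    pc, list(chain = "A", resno = 1), list(chain = "A", resno = 6))$types)
})

test_that("contact typing is symmetric and rejects sequence-adjacent pairs", {
  g <- make_dimer(sandwich_spec("parallel_dimer"))
  st <- g$structure
  ri <- list(chain = "A", resno = 40); rj <- list(chain = "B", resno = 25)
  e1 <- classify_contact(st, ri, rj); e2 <- classify_contact(st, rj, ri)
  if (!is.null(e1) || !is.null(e2)) {
    expect_setequal(e1$types, e2$types)
    expect_equal(e1$min_distance, e2$min_distance)
  }
  expect_null(classify_contact(st, list(chain = "A", resno = 10),
                               list(chain = "A", resno = 11)))
  expect_error(classify_contact(st, list(chain = "A", resno = 10),
                                list(chain = "A", resno = 10)), "distinct")
})

test_that("the BC/EF core network has lateral and backbone-typed edges only for poly-Ala", {
  g <- make_ig_domain(sandwich_spec("V_set", sequence_mode = "poly_ala",
                                    atom_mode = "full"))
  ann <- label_ig_strands(detect_strands(g$structure, "A"))
  net <- core_network(g$structure, ann)
  expect_s3_class(net, "InteractionNetwork")
  expect_gt(length(net$edges), 0)
  classes <- vapply(net$edges, `[[`, "", "edge_class")
  expect_true("lateral" %in% classes)
  types <- unique(unlist(lapply(net$edges, `[[`, "types")))
  # no side-chain-dependent interaction types without side chains
  expect_true(all(types %in% c("vdw", "hbond")))
  expect_true(all(vapply(net$nodes$strand, function(s)
    s %in% c("B", "C", "E", "F"), logical(1))))
})

test_that("the decorated core contains the B-F cysteine pair position", {
  g <- make_ig_domain(sandwich_spec("V_set", atom_mode = "full"))
  ann <- label_ig_strands(detect_strands(g$structure, "A"))
  net <- core_network(g$structure, ann)
  expect_true(any(net$nodes$resid == "CYS" & net$nodes$strand == "B"))
  expect_true(any(net$nodes$resid == "CYS" & net$nodes$strand == "F"))
})

test_that("networks are invariant under rigid motion of the structure", {
  g <- make_ig_domain(sandwich_spec("C1_set", atom_mode = "full"))
  ann <- label_ig_strands(detect_strands(g$structure, "A"))
  net1 <- core_network(g$structure, ann)
  set.seed(33)
  st2 <- move_structure(g$structure, random_rotation(), c(-12, 40, 3))
  net2 <- core_network(st2, label_ig_strands(detect_strands(st2, "A")))
  id <- function(net) sort(vapply(net$edges, igproto:::edge_id, ""))
  expect_equal(id(net1), id(net2))
})

test_that("network comparison counts conserved edges exactly", {
  g <- make_ig_domain(sandwich_spec("V_set", atom_mode = "full"))
  ann <- label_ig_strands(detect_strands(g$structure, "A"))
  net <- core_network(g$structure, ann)
  idmap <- data.frame(chain_i = net$nodes$chain, key_i = net$nodes$key,
                      chain_j = net$nodes$chain, key_j = net$nodes$key,
                      stringsAsFactors = FALSE)
  cmp <- compare_networks(net, net, idmap)
  expect_equal(cmp$conserved_edge_fraction, 1)
  expect_true(all(cmp$node_status$conserved))
  # seeded deletion of 20% of the edges gives an exactly predictable fraction
  set.seed(7)
  ndrop <- round(0.2 * length(net$edges))
  net2 <- net
  net2$edges <- net$edges[-sample(seq_along(net$edges), ndrop)]
  cmp2 <- compare_networks(net, net2, idmap)
  expect_equal(cmp2$conserved_edge_fraction,
               (length(net$edges) - ndrop) / length(net$edges))
  expect_error(compare_networks(net, net, idmap[1:2, ]), "50%")
  expect_error(compare_networks(net, net, idmap[0, ]), "empty")
})

test_that("the quaternary network of an exact-C2 homodimer is symmetric", {
  g <- make_dimer(sandwich_spec("parallel_dimer"))
  st <- g$structure
  net <- dimer_network(st, ig_domain(st, "A"), ig_domain(st, "B"))
  expect_gt(length(net$edges), 0)
  resn <- sort(unique(st$atoms$resno))
  c2map <- data.frame(chain_i = rep(c("A", "B"), each = length(resn)),
                      key_i = as.character(c(resn, resn)),
                      chain_j = rep(c("B", "A"), each = length(resn)),
                      key_j = as.character(c(resn, resn)),
                      stringsAsFactors = FALSE)
  cmp <- compare_networks(net, net, c2map)
  expect_equal(cmp$conserved_edge_fraction, 1)
})
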