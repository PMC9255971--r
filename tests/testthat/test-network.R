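det_row <- function(pid, a, b, sev = "C", kind = "DDI") {
  data.frame(patient_id = pid, drug_a = pmin(a, b), drug_b = pmax(a, b),
             severity = rep_len(sev, length(pid)),
             kind = rep_len(kind, length(pid)),
             major = rep_len(sev %in% c("D", "X"), length(pid)),
             stringsAsFactors = FALSE)
}

triangle_annotation <- function() {
  fml <- formulary(c("furosemide", "lisinopril", "warfarin"),
                   list("C03CA01", "C09AA03", "B01AA03"))
  meds <- normalize_and_dedupe(medication_log(
    rep("p1", 3), c("furosemide", "lisinopril", "warfarin")))
  co <- med_cohort(tiny_patients("p1"), meds)
  classify_cohort(co, fml)
}

test_that("detections aggregate into the expected subgroup triangle", {
  ann <- triangle_annotation()
  det <- rbind(det_row("p1", "furosemide", "lisinopril"),
               det_row("p1", "furosemide", "warfarin"),
               det_row("p2", "lisinopril", "warfarin"))
  net <- build_network(det, 2, ann)
  expect_setequal(net$nodes, c("B01", "C03", "C09"))
  expect_equal(nrow(net$edges), 3)
  expect_equal(net$self_pairs, 0)
  m <- compute_metrics(net)
  expect_equal(m$density, 1.0)
  expect_equal(m$diameter, 1L)
  expect_equal(m$triadic_closure, 1.0)
})

test_that("no detections give an empty network", {
  net <- build_network(det_row(character(0), character(0), character(0)),
                       "medication")
  expect_length(net$nodes, 0)
  m <- compute_metrics(net)
  expect_equal(m$n_nodes, 0)
  expect_equal(m$density, 0)
})

test_that("path graph metrics follow the closed forms", {
  det <- rbind(det_row("p1", "a", "b"), det_row("p1", "b", "c"))
  net <- build_network(det, "medication")
  m <- compute_metrics(net)
  expect_equal(m$density, 2 / 3)
  expect_equal(m$diameter, 2L)
  expect_equal(m$triadic_closure, 0)
})

test_that("same-subgroup and unmapped detections are tallied, not edges", {
  fml <- formulary(c("ibuprofen", "naproxen", "warfarin"),
                   list("M01AE01", "M01AE02", "B01AA03"))
  meds <- normalize_and_dedupe(medication_log(
    rep("p1", 3), c("ibuprofen", "naproxen", "warfarin")))
  co <- med_cohort(tiny_patients("p1"), meds)
  ann <- classify_cohort(co, fml)
  det <- rbind(det_row("p1", "ibuprofen", "naproxen"),   # same level-2 class
               det_row("p1", "ibuprofen", "warfarin"),
               det_row("p1", "ghost drug", "warfarin"))  # unclassified
  expect_message(net <- build_network(det, 2, ann), "unmapped")
  expect_equal(net$self_pairs, 1)
  expect_equal(net$unmapped, 1)
  expect_equal(nrow(net$edges), 1)
  # conservation: weights + self-pairs + unmapped = detections
  expect_equal(sum(net$edges$weight) + net$self_pairs + net$unmapped,
               nrow(det))
})

test_that("aggregated adjacency equals hand aggregation on a 12-detection fixture", {
  generics <- c("g1", "g2", "g3", "g4", "g5")
  codes <- c("C10AA01", "C10AA02", "C09AA01", "C07AB01", "A10BA01")
  fml <- formulary(generics, as.list(codes))
  meds <- normalize_and_dedupe(medication_log(rep("p1", 5), generics))
  co <- med_cohort(tiny_patients("p1"), meds)
  ann <- classify_cohort(co, fml)
  det <- rbind(
    det_row("p1", "g1", "g3"), det_row("p2", "g1", "g3"),
    det_row("p3", "g2", "g3"),                       # C10-C09 again
    det_row("p1", "g1", "g4"), det_row("p2", "g2", "g4"),
    det_row("p1", "g3", "g4"), det_row("p2", "g3", "g4"),
    det_row("p3", "g3", "g4"),
    det_row("p1", "g4", "g5"),
    det_row("p1", "g1", "g2"),                       # same class C10
    det_row("p1", "g3", "g5"), det_row("p2", "g5", "g3")
  )
  net <- build_network(det, 2, ann)
  w <- function(a, b) {
    e <- net$edges
    e$weight[e$source == min(a, b) & e$target == max(a, b)]
  }
  expect_equal(w("C10", "C09"), 3)
  expect_equal(w("C10", "C07"), 2)
  expect_equal(w("C09", "C07"), 3)
  expect_equal(w("C07", "A10"), 1)
  expect_equal(w("C09", "A10"), 2)
  expect_equal(net$self_pairs, 1)
  expect_equal(sum(net$edges$weight) + net$self_pairs + net$unmapped, 12)
})

test_that("metrics agree with exhaustive oracles on random graphs up to 15 nodes", {
  set.seed(61)
  for (rep in 1:12) {
    n <- sample(2:15, 1)
    p <- stats::runif(1, 0.15, 0.7)
    edges <- random_edges(n, p)
    if (nrow(edges) == 0) next
    net <- as_network(edges)
    m <- compute_metrics(net)
    adj <- oracle_adjacency(net$nodes, edges)
    expect_equal(m$density, sum(adj) / (nrow(adj) * (nrow(adj) - 1)))
    expect_equal(m$diameter, oracle_diameter_largest(adj))
    expect_equal(m$triadic_closure, oracle_transitivity(adj))
    comp <- oracle_components(adj)
    expect_equal(m$n_components, max(comp))
  }
})

test_that("metrics are invariant under node relabeling", {
  set.seed(73)
  edges <- random_edges(10, 0.4)
  net <- as_network(edges)
  m1 <- compute_metrics(net)
  perm <- sample(net$nodes)
  relabel <- stats::setNames(perm, net$nodes)
  e2 <- data.frame(source = unname(relabel[edges$source]),
                   target = unname(relabel[edges$target]),
                   weight = edges$weight, stringsAsFactors = FALSE)
  swap <- e2$source > e2$target
  tmp <- e2$source[swap]; e2$source[swap] <- e2$target[swap]
  e2$target[swap] <- tmp
  m2 <- compute_metrics(as_network(e2))
  for (f in c("density", "diameter", "triadic_closure", "n_components")) {
    expect_equal(m1[[f]], m2[[f]], label = f)
  }
})

test_that("chord matrix thresholds, symmetry and conservation hold", {
  ann <- triangle_annotation()
  det <- rbind(
    do.call(rbind, replicate(25, det_row("p", "furosemide", "lisinopril"),
                             simplify = FALSE)),
    do.call(rbind, replicate(5, det_row("p", "furosemide", "warfarin"),
                             simplify = FALSE))
  )
  m20 <- chord_matrix(det, 2, ann, min_count = 20)
  expect_equal(sort(rownames(m20)), rownames(m20))
  expect_equal(m20["C03", "C09"], 25)
  expect_false("B01" %in% rownames(m20)) # filtered pair drops its nodes
  m1 <- chord_matrix(det, 2, ann, min_count = 1)
  expect_equal(sum(m1), 2 * nrow(det))
  expect_true(all(m1 == t(m1)))
  expect_true(all(diag(m1) == 0))
  expect_error(chord_matrix(det, 2, ann, min_count = 0), "min_count")
})

test_that("seven-pair fixture filters to the hand-computed retained set", {
  counts <- c(5, 3, 3, 2, 1, 4, 3)
  pairs <- list(c("a", "b"), c("a", "c"), c("a", "d"), c("b", "c"),
                c("b", "d"), c("c", "d"), c("c", "e"))
  det <- do.call(rbind, lapply(seq_along(pairs), function(i) {
    do.call(rbind, replicate(counts[i],
                             det_row("p", pairs[[i]][1], pairs[[i]][2]),
                             simplify = FALSE))
  }))
  m <- chord_matrix(det, "medication", min_count = 3)
  retained <- which(upper.tri(m) & m > 0)
  expect_equal(sum(m[upper.tri(m)] > 0), 5) # hand count: pairs with >= 3
  expect_equal(m["a", "b"], 5)
  expect_equal(m["b", "c"], 0)
})
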