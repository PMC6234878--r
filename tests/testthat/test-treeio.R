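test_that("newick and nexus tree sets parse, validate and round-trip", {
  tf <- withr::local_tempfile(fileext = ".nwk")
  writeLines("(A:1,B:1);", tf)
  ts <- read_tree_set(tf)
  expect_length(ts, 1)
  expect_setequal(ts[[1]]$tip.label, c("A", "B"))
  expect_equal(ts[[1]]$edge.length, c(1, 1))

  # nexus with a translate table resolves numeric labels
  nx <- withr::local_tempfile(fileext = ".nex")
  writeLines(c("#NEXUS",
               "begin trees;",
               "\ttranslate",
               "\t\t1 A,",
               "\t\t2 B",
               "\t;",
               "\ttree t1 = (1:1,2:1);",
               "end;"), nx)
  tsn <- read_tree_set(nx)
  expect_setequal(tsn[[1]]$tip.label, c("A", "B"))

  # write-then-read round trip across a jittered posterior set
  base <- simulate_bd_tree(1, 0.2, 20, seed = 11)
  trees <- simulate_posterior_set(base, n_trees = 10, jitter = 0.1, seed = 2)
  out <- withr::local_tempfile(fileext = ".nwk")
  write_tree_set(trees, out)
  back <- read_tree_set(out)
  expect_length(back, 10)
  for (i in seq_len(10)) {
    expect_equal(suppressWarnings(ape::dist.topo(back[[i]], trees[[i]])), 0,
                 ignore_attr = TRUE)
    # 9 significant digits bound the round-trip error at 5e-9 relative
    expect_equal(sort(back[[i]]$edge.length), sort(trees[[i]]$edge.length),
                 tolerance = 5e-9)
  }
})

test_that("malformed and inconsistent tree files are rejected with context", {
  tf <- withr::local_tempfile(fileext = ".nwk")
  writeLines(c("(A:1,B:1);", "(A:1,B:1"), tf)
  expect_error(read_tree_set(tf), "line 2", class = "phyniche_parse_error")

  dup <- structure(list(ape::read.tree(text = "(A:1,A:1);")),
                   class = "multiPhylo")
  expect_error(validate_tree_set(dup), class = "phyniche_validation_error")

  mixed <- structure(list(ape::read.tree(text = "(A:1,B:1);"),
                          ape::read.tree(text = "(A:1,C:1);")),
                     class = "multiPhylo")
  expect_error(validate_tree_set(mixed), class = "phyniche_validation_error")
})

test_that("cophenetic distances equal path sums and a graph-traversal oracle", {
  expect_equal(cophenetic_matrix(ape::read.tree(text = "(A:1,B:1);"))["A", "B"], 2)
  D <- cophenetic_matrix(ape::read.tree(text = "((A:1,B:1):1,C:2);"))
  expect_equal(D["A", "B"], 2)
  expect_equal(D["A", "C"], 4)
  expect_equal(D["B", "C"], 4)
  expect_true(isSymmetric(D))
  expect_true(all(diag(D) == 0))

  # independent oracle: breadth-first path sums on the edge list
  tr <- simulate_bd_tree(1, 0.3, 20, seed = 5)
  D <- cophenetic_matrix(tr)
  ntot <- ape::Ntip(tr) + tr$Nnode
  adj <- vector("list", ntot)
  for (e in seq_len(nrow(tr$edge))) {
    a <- tr$edge[e, 1]; b <- tr$edge[e, 2]; w <- tr$edge.length[e]
    adj[[a]] <- rbind(adj[[a]], c(b, w))
    adj[[b]] <- rbind(adj[[b]], c(a, w))
  }
  bfs_dist <- function(src) {
    d <- rep(NA_real_, ntot)
    d[src] <- 0
    queue <- src
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (j in seq_len(NROW(adj[[v]]))) {
        u <- adj[[v]][j, 1]
        if (is.na(d[u])) {
          d[u] <- d[v] + adj[[v]][j, 2]
          queue <- c(queue, u)
        }
      }
    }
    d
  }
  for (i in seq_len(ape::Ntip(tr))) {
    expect_equal(unname(D[tr$tip.label[i], tr$tip.label]),
                 bfs_dist(i)[seq_len(ape::Ntip(tr))], tolerance = 1e-12)
  }
})

test_that("cophenetic matrices satisfy the four-point condition", {
  tr <- simulate_bd_tree(1, 0, 8, seed = 9)
  D <- cophenetic_matrix(tr)
  tips <- rownames(D)
  for (q in utils::combn(tips, 4, simplify = FALSE)) {
    s <- sort(c(D[q[1], q[2]] + D[q[3], q[4]],
                D[q[1], q[3]] + D[q[2], q[4]],
                D[q[1], q[4]] + D[q[2], q[3]]))
    expect_lte(s[3] - s[2], 1e-9)
  }
})

test_that("lambda transform preserves depths and hits its limits", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  expect_equal(lambda_transform(tr, 1)$edge.length, tr$edge.length)

  star <- lambda_transform(tr, 0)
  internal <- star$edge[, 2] > ape::Ntip(star)
  expect_true(all(star$edge.length[internal] == 0))
  expect_equal(max(ape::node.depth.edgelength(star)), 2)

  big <- simulate_bd_tree(1, 0.2, 20, seed = 3)
  for (lam in c(0, 0.3, 0.5, 0.9)) {
    tl <- lambda_transform(big, lam)
    d0 <- ape::node.depth.edgelength(big)[1:20]
    d1 <- ape::node.depth.edgelength(tl)[1:20]
    expect_equal(d1, d0, tolerance = 1e-10)
  }
  # monotone: internal branch mass shrinks (and, because depths are
  # preserved, total length grows) as lambda decreases
  internal <- big$edge[, 2] > ape::Ntip(big)
  int_lens <- vapply(c(1, 0.7, 0.4, 0.1, 0), function(l) {
    sum(lambda_transform(big, l)$edge.length[internal])
  }, numeric(1))
  expect_true(all(diff(int_lens) <= 1e-9))
  tot_lens <- vapply(c(1, 0.7, 0.4, 0.1, 0), function(l) {
    sum(lambda_transform(big, l)$edge.length)
  }, numeric(1))
  expect_true(all(diff(tot_lens) >= -1e-9))

  nonultra <- ape::read.tree(text = "(A:1,B:2);")
  expect_error(lambda_transform(nonultra, 0.5),
               class = "phyniche_validation_error")
})

test_that("anchors resolve to MRCAs with correct monophyly flags", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  res <- resolve_anchors(tr, node_anchor(c("A", "B"), "cherry"))
  expect_equal(res$node, ape::getMRCA(tr, c("A", "B")))
  expect_true(res$monophyletic)

  res2 <- resolve_anchors(tr, node_anchor(c("A", "C")))
  expect_equal(res2$node, ape::Ntip(tr) + 1L) # root
  expect_false(res2$monophyletic)

  expect_error(node_anchor("A"), class = "phyniche_validation_error")

  # superset property across a jittered tree set with NNI edits
  base <- simulate_bd_tree(1, 0.2, 30, seed = 8)
  anchors <- lapply(1:4, function(i) {
    node <- ape::Ntip(base) + 1 + i * 5
    node_anchor(phyniche:::clade_tips(base, node), paste0("n", i))
  })
  trees <- simulate_posterior_set(base, 20, jitter = 0.15, nni_prop = 0.3,
                                  seed = 4)
  for (tr2 in trees) {
    res <- resolve_anchors(tr2, anchors)
    for (j in seq_len(nrow(res))) {
      desc <- phyniche:::clade_tips(tr2, res$node[j])
      expect_true(all(anchors[[j]]$tips %in% desc))
    }
  }
})
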