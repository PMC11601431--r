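# Residue graphs and the attention network: membership, gradients,
# ensembles, transfer learning.

tiny_graph <- function(n = 6, width = 7, seed = 3, label = 1.3) {
  set.seed(seed)
  structure(list(x = matrix(rnorm(n * width), n, width),
                 edges = cbind(seq_len(n - 1), seq_len(n - 1) + 1L),
                 label = label, aa = "ASP"),
            class = "residue_graph")
}

shared_graphs <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ds <- shared_dataset()
      cache <<- build_graphs(ds$table[1:24, ], ds$structures)
    }
    cache
  }
})

test_that("graph nodes are exactly the atoms within the sphere, brute force", {
  ds <- shared_dataset()
  for (id in names(ds$structures)[c(1, 7)]) {
    s <- read_structure(ds$structures[[id]], source_id = id)
    site <- host_site(s)
    g <- build_graph(s, site, radius = 10)
    d <- protpka:::dist_to(site$anchor_point, atom_coords(s))
    expect_equal(nrow(g$x), sum(d <= 10))
    # and every pairwise edge obeys the cutoff, brute force
    dm <- protpka:::dist_mat(g$coords, g$coords)
    expect_true(all(dm[g$edges] <= 4.0))
    expect_equal(nrow(g$edges), sum(dm <= 4.0 & upper.tri(dm)))
  }
})

test_that("edge rule on a linear three-atom chain keeps only adjacent pairs", {
  at <- data.frame(name = "CA", element = "C", resname = "GLY", chain = "A",
                   resno = 1:4, insert = "", x = c(0, 3, 6, 9), y = 0, z = 0,
                   occ = 1)
  s <- protpka:::atoms_to_structure(at)
  site <- structure(list(chain = "A", resno = 2L, insert = "", aa = "ASP",
                         res_key = "A|2|", anchor_point = c(3, 0, 0),
                         structure_id = "chain"),
                    class = "titratable_site")
  g <- build_graph(s, site, radius = 10, edge_cutoff = 4.0)
  expect_equal(nrow(g$x), 4L)
  expect_equal(g$edges[order(g$edges[, 1]), ], cbind(1:3, 2:4),
               ignore_attr = TRUE)
  expect_error(build_graph(s, site, radius = 1), "too sparse")
})

test_that("rigid motion leaves the graph isomorphic with identical features", {
  ds <- shared_dataset()
  s <- read_structure(ds$structures[[3]], source_id = "g3")
  site <- host_site(s)
  g1 <- build_graph(s, site)
  R <- rotation_matrix("x", 45) %*% rotation_matrix("z", 120)
  s2 <- set_atom_coords(s, rigid_transform(atom_coords(s), R, c(-4, 2, 9)))
  g2 <- build_graph(s2, host_site(s2))
  expect_identical(g1$atom_ids, g2$atom_ids)
  expect_equal(g1$x, g2$x)
  expect_equal(g1$edges, g2$edges)
})

test_that("analytic gradients match finite differences", {
  g <- tiny_graph()
  cfg <- gat_config(channels = 5L, hidden = c(4L, 3L), dropout = 0)
  set.seed(9)
  par <- protpka:::gat_init_params(7L, cfg)
  fw <- protpka:::gat_forward(g, par, cfg, keep_cache = TRUE)
  gr <- protpka:::gat_backward(g, par, cfg, fw$cache, 1)
  eps <- 1e-6
  fd <- function(mutate) {
    p1 <- mutate(par, eps); p2 <- mutate(par, -eps)
    (protpka:::gat_forward(g, p1, cfg)$y -
       protpka:::gat_forward(g, p2, cfg)$y) / (2 * eps)
  }
  cases <- list(
    list(g = gr$conv[[1]]$W[2, 3],
         m = function(p, e) { p$conv[[1]]$W[2, 3] <- p$conv[[1]]$W[2, 3] + e; p }),
    list(g = gr$conv[[2]]$a_src[1],
         m = function(p, e) { p$conv[[2]]$a_src[1] <- p$conv[[2]]$a_src[1] + e; p }),
    list(g = gr$conv[[2]]$a_dst[4],
         m = function(p, e) { p$conv[[2]]$a_dst[4] <- p$conv[[2]]$a_dst[4] + e; p }),
    list(g = gr$conv[[3]]$b[2],
         m = function(p, e) { p$conv[[3]]$b[2] <- p$conv[[3]]$b[2] + e; p }),
    list(g = gr$mlp$W1[3, 2],
         m = function(p, e) { p$mlp$W1[3, 2] <- p$mlp$W1[3, 2] + e; p }),
    list(g = gr$mlp$b3,
         m = function(p, e) { p$mlp$b3 <- p$mlp$b3 + e; p }))
  for (cs in cases)
    expect_equal(cs$g, fd(cs$m), tolerance = 1e-5)
})

test_that("constant labels are fitted to a constant prediction", {
  gs <- lapply(1:12, function(i) tiny_graph(seed = i, label = 0.7))
  m <- train_gat(gs, gat_config(epochs = 150L, lr = 1e-2, dropout = 0),
                 seed = 1, validation_frac = 0)
  expect_true(all(abs(predict(m, gs) - 0.7) < 0.1))
})

test_that("training is reproducible and guards the feature width", {
  gs <- shared_graphs()[1:10]
  cfg <- gat_config(epochs = 15L, dropout = 0)
  m1 <- train_gat(gs, cfg, seed = 4)
  m2 <- train_gat(gs, cfg, seed = 4)
  expect_identical(m1$params, m2$params)
  bad <- tiny_graph(width = 7)
  expect_error(predict(m1, bad), "width mismatch")
  expect_error(train_gat(c(gs, list(bad)), cfg), "widths")
})

test_that("a k=1 ensemble equals its single member and the shift arithmetic holds", {
  gs <- shared_graphs()[1:20]
  ens <- train_ensemble(gs, k = 1L, gat_config(epochs = 10L), seed = 5)
  p_ens <- predict_ensemble(ens, gs[1:4])
  aa <- vapply(gs[1:4], function(g) g$aa, character(1))
  p_one <- model_pka(aa) + predict(ens$members[[1]], gs[1:4])
  expect_equal(p_ens, p_one)
  expect_error(predict_ensemble(structure(list(members = list()),
                                          class = "gat_ensemble"), gs[[1]]),
               "empty")

  # members emitting constant shifts 1, 2, 3 average to model pKa + 2
  cfg <- gat_config()
  const_member <- function(shift) {
    p <- protpka:::gat_init_params(ncol(gs[[1]]$x), cfg)
    for (l in seq_along(p$conv)) {
      p$conv[[l]]$W[] <- 0; p$conv[[l]]$a_src[] <- 0
      p$conv[[l]]$a_dst[] <- 0; p$conv[[l]]$b[] <- 0
    }
    p$mlp$W1[] <- 0; p$mlp$W2[] <- 0; p$mlp$W3[] <- 0
    p$mlp$b1[] <- 0; p$mlp$b2[] <- 0; p$mlp$b3 <- shift
    structure(list(params = p, config = cfg, width = ncol(gs[[1]]$x)),
              class = "gat_model")
  }
  ens3 <- structure(list(members = lapply(1:3, const_member), config = cfg),
                    class = "gat_ensemble")
  asp_graph <- gs[[which(vapply(gs, function(g) g$aa, character(1)) == "ASP")[1]]]
  expect_equal(predict_ensemble(ens3, asp_graph), 3.7 + 2.0)
})

test_that("two ensembles from one master seed share member assignments", {
  gs <- shared_graphs()[1:20]
  e1 <- train_ensemble(gs, k = 2L, gat_config(epochs = 5L), seed = 9)
  e2 <- train_ensemble(gs, k = 2L, gat_config(epochs = 5L), seed = 9)
  expect_identical(e1$folds, e2$folds)
  expect_identical(e1$members[[1]]$params, e2$members[[1]]$params)
})

test_that("the freeze contract holds bitwise and zero-epoch fine-tuning is identity", {
  gs <- shared_graphs()[1:20]
  cfg <- gat_config(epochs = 8L, lr = 5e-3)
  tr <- pretrain_finetune(gs, gs, cfg, frozen_layers = 2L, seed = 3)
  expect_identical(tr$pretrained$params$conv[[1]], tr$finetuned$params$conv[[1]])
  expect_identical(tr$pretrained$params$conv[[2]], tr$finetuned$params$conv[[2]])
  expect_false(identical(tr$pretrained$params$conv[[3]],
                         tr$finetuned$params$conv[[3]]))
  expect_error(pretrain_finetune(gs, gs, cfg, frozen_layers = 3L), "frozen")

  cfg0 <- gat_config(epochs = 0L)
  tr0 <- pretrain_finetune(gs, gs, cfg, frozen_layers = 0L, seed = 3,
                           fine_config = cfg0)
  expect_identical(tr0$pretrained$params, tr0$finetuned$params)
})

test_that("fine-tuning on the truth improves on a biased pretraining", {
  # pretraining labels carry a constant bias; fine-tuning must undo it
  gs <- shared_graphs()
  biased <- lapply(gs, function(g) { g$label <- g$label + 0.5; g })
  cfg <- gat_config(epochs = 60L, lr = 5e-3, dropout = 0)
  tr <- pretrain_finetune(biased, gs, cfg, frozen_layers = 0L, seed = 7)
  lab <- vapply(gs, function(g) g$label, numeric(1))
  rmse_pre <- sqrt(mean((predict(tr$pretrained, gs) - lab)^2))
  rmse_fine <- sqrt(mean((predict(tr$finetuned, gs) - lab)^2))
  expect_lt(rmse_fine, rmse_pre)
})
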