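test_that("gain branch is the terminal branch for singletons and the MRCA stem otherwise", {
  tr <- tree4()
  a <- match("A", tr$phy$tip.label)
  expect_equal(infer_gain_branch(c(A = 1, B = 0, C = 0, D = 0), tr), a)
  # cherry (A,B): branch subtending their MRCA
  mrca_ab <- ape::getMRCA(tr$phy, match(c("A", "B"), tr$phy$tip.label))
  expect_equal(infer_gain_branch(c(A = 1, B = 1, C = 0, D = 0), tr), mrca_ab)
  # {A,D} spans the root: the root-stem branch hosts the gain
  expect_equal(infer_gain_branch(c(A = 1, B = 0, C = 0, D = 1), tr), tr$root)
  expect_error(infer_gain_branch(c(A = 0, B = 0, C = 0, D = 0), tr), "all-absent")
})

test_that("a root-spanning family on a tree without a root stem errors with guidance", {
  tr <- timetree(ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);"))
  expect_error(infer_gain_branch(c(A = 1, B = 0, C = 0, D = 1), tr),
               "root stem")
})

test_that("loss branches match the spec's 4-tip cases", {
  tr <- tree4()
  lab <- tr$phy$tip.label
  expect_equal(infer_loss_branches(c(A = 1, B = 1, C = 1, D = 1), tr), integer(0))
  expect_equal(infer_loss_branches(c(A = 1, B = 1, C = 0, D = 1), tr),
               match("C", lab))
  expect_equal(sort(infer_loss_branches(c(A = 1, B = 0, C = 0, D = 1), tr)),
               sort(match(c("B", "C"), lab)))
})

test_that("loss placement equals the exhaustive minimal irreversible history", {
  set.seed(21)
  # all patterns on several random 4- and 5-tip trees, random patterns on 6
  for (n in 4:6) {
    for (rep in 1:3) {
      tr <- rand_timetree(n, stem = TRUE)
      pats <- all_patterns(tr$phy$tip.label)
      if (n == 6) pats <- pats[sample(nrow(pats), 20), , drop = FALSE]
      for (r in seq_len(nrow(pats))) {
        st <- pats[r, ]
        got <- infer_loss_branches(st, tr)
        orc <- oracle_dollo(st, tr)
        expect_length(orc$branch_sets, 1)      # minimal history is unique
        expect_equal(sort(got), orc$branch_sets[[1]])
        expect_equal(length(got), orc$min_losses)
      }
    }
  }
})

test_that("loss bounds follow the terminal-loss rule", {
  tr <- tree4()
  m <- rbind(s  = c(A = 1, B = 0, C = 0, D = 0),   # singleton
             ch = c(A = 1, B = 1, C = 0, D = 0),   # 2-tip clade, both present
             sp = c(A = 1, B = 0, C = 0, D = 1))   # 4-tip clade
  b <- loss_bounds(m, tr)
  expect_equal(b$min_losses, c(0L, 0L, 0L))
  expect_equal(b$max_losses[b$family == "s"], 0L)
  expect_equal(b$max_losses[b$family == "ch"], 0L)
  expect_equal(b$max_losses[b$family == "sp"], 2L)
  expect_equal(attr(b, "total_max"), 2L)

  # 5-tip least-inclusive clade: max = 3
  tr5 <- timetree(ape::read.tree(
    text = "(((A:1,B:1):1,(C:1.5,(D:1,E:1):0.5):0.5):1,F:3):1;"))
  b5 <- loss_bounds(rbind(f = c(A = 1, B = 0, C = 0, D = 0, E = 1, F = 0)), tr5)
  expect_equal(b5$clade_size, 5L)
  expect_equal(b5$max_losses, 3L)
})

test_that("dollo_map invariants: one gain per family, counts within bounds, containment", {
  tr <- fixture_tree35()
  sim <- sim_gainloss_matrix(tr, gain_intensity = 0.02, loss_rate = 2e-3,
                             seed = 30)
  dm <- dollo_map(sim$matrix, tr, n_reps = 25, seed = 3)
  ev <- dm$events
  gains <- ev[ev$type == "gain", ]
  expect_equal(nrow(gains), dm$n_families * dm$n_reps)
  expect_true(all(table(gains$replicate) == dm$n_families))
  # singletons never lose
  singletons <- rownames(sim$matrix)[rowSums(sim$matrix) == 1]
  expect_true(all(dm$loss_counts[singletons] == 0))
  # min <= inferred <= max
  b <- dm$bounds
  expect_true(all(dm$loss_counts[b$family] >= b$min_losses))
  expect_true(all(dm$loss_counts[b$family] <= b$max_losses))
  # event-time containment on the event's branch
  br <- tr$branches[match(ev$branch, tr$branches$branch), ]
  expect_true(all(ev$time >= br$end - 1e-9 & ev$time <= br$start + 1e-9))
  # per family and replicate, the gain is older than every loss
  key <- paste(ev$replicate, ev$family)
  gtime <- gains$time[match(key, paste(gains$replicate, gains$family))]
  losses <- ev$type == "loss"
  expect_true(all(ev$time[losses] < gtime[losses]))
})

test_that("branch assignments are replicate- and seed-invariant; times are seeded", {
  tr <- tree4()
  m <- presence_matrix(rbind(f1 = c(A = 1, B = 1, C = 0, D = 1),
                             f2 = c(A = 1, B = 0, C = 0, D = 0)))
  d1 <- dollo_map(m, tr, n_reps = 5, seed = 9)
  d2 <- dollo_map(m, tr, n_reps = 5, seed = 9)
  expect_identical(d1$events, d2$events)          # determinism under a seed
  d3 <- dollo_map(m, tr, n_reps = 5, seed = 10)
  expect_identical(d1$gain_branch, d3$gain_branch)
  expect_identical(d1$loss_branches, d3$loss_branches)
  expect_false(identical(d1$events$time, d3$events$time))
  # per-branch counts identical in every replicate
  ev <- d1$events
  per_rep <- split(ev[c("type", "branch")], ev$replicate)
  norm <- lapply(per_rep, function(d) {
    d <- d[order(d$branch, d$type), ]
    rownames(d) <- NULL
    d
  })
  expect_length(unique(norm), 1)
})

test_that("event times are uniform on the branch interval", {
  # gain on a deep branch: 10,000 replicate draws against U(start, end)
  tr <- tree4()
  m <- presence_matrix(rbind(f = c(A = 1, B = 1, C = 1, D = 1)))
  dm <- dollo_map(m, tr, n_reps = 10000, seed = 4)
  t_g <- dm$events$time[dm$events$type == "gain"]
  expect_gt(min(t_g), 200)
  expect_lt(max(t_g), 250)
  expect_equal(mean(t_g), 225, tolerance = 0.01)
  ks <- stats::ks.test(t_g, "punif", 200, 250)
  expect_gt(ks$p.value, 0.01)
})

test_that("zero-length branches put events exactly at the node age", {
  phy <- ape::read.tree(text = "((A:0,B:100):100,(C:100,D:100):100):50;")
  tr <- timetree(phy)
  m <- presence_matrix(rbind(f = c(A = 1, B = 0, C = 0, D = 0)))
  dm <- dollo_map(m, tr, n_reps = 10, seed = 1)
  expect_true(all(dm$events$time == tr$ages[match("A", tr$phy$tip.label)] +
                    tr$branches$duration[tr$branches$branch ==
                                           match("A", tr$phy$tip.label)]))
})

test_that("exponential loss timing is accepted and recorded", {
  tr <- tree4()
  m <- presence_matrix(rbind(f1 = c(A = 1, B = 1, C = 0, D = 1)))
  dm <- dollo_map(m, tr, n_reps = 200, seed = 2,
                  loss_timing = "exponential", loss_timing_rate = 0.05)
  expect_equal(dm$loss_timing, "exponential")
  lt <- dm$events$time[dm$events$type == "loss"]
  brC <- tr$branches[tr$branches$branch == match("C", tr$phy$tip.label), ]
  expect_true(all(lt >= brC$end & lt <= brC$start))
  # start-anchored exponential concentrates mass toward the older end
  expect_gt(mean(lt), (brC$start + brC$end) / 2)
})
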