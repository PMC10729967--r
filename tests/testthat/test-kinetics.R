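test_that("the connection rule truth table holds exactly", {
  links <- make_links(2, list(c(1, 2, 5, 0)))
  expect_equal(igraph::ecount(connectivity_graph(links, 2)), 1)  # 5 HB connect
  links <- make_links(2, list(c(1, 2, 4, 1)))
  expect_equal(igraph::ecount(connectivity_graph(links, 2)), 0)  # both fail
  links <- make_links(2, list(c(1, 2, 0, 2)))
  expect_equal(igraph::ecount(connectivity_graph(links, 2)), 1)  # 2 phobic
})

test_that("pairwise links count registry bonds and hydrophobic contacts", {
  traj <- scripted_trajectory(4, list(
    list(list(members = c(1, 2), class = "sheet"))
  ), hb_per_interface = 5)
  fr <- traj$frames[[1]]
  links <- pairwise_links(fr, traj$beads, default_table)
  l12 <- links[links$a == 1 & links$b == 2, ]
  expect_equal(l12$n_hbonds, 5)
  expect_gte(l12$n_hydrophobic, 0)
  expect_equal(sum(links$n_hbonds[!(links$a == 1 & links$b == 2)]), 0)
  # inter-peptide hydrogen-bond totals equal the registry count
  expect_equal(sum(links$n_hbonds), sum(fr$hb_partner > 0) / 2)
  # two isolated peptides share nothing
  l34 <- links[links$a == 3 & links$b == 4, ]
  expect_equal(unlist(l34[c("n_hbonds", "n_hydrophobic")]),
               c(n_hbonds = 0, n_hydrophobic = 0))
})

test_that("cluster extraction matches a transitive-closure oracle", {
  g <- connectivity_graph(make_links(200, list()), 200)
  expect_equal(length(clusters(g)), 200)
  expect_true(all(lengths(clusters(g)) == 1))

  path6 <- make_links(6, lapply(1:5, function(k) c(k, k + 1, 5, 0)))
  cl <- clusters(connectivity_graph(path6, 6))
  expect_equal(cl, list(1:6))

  set.seed(61)
  for (k in 1:100) {
    n <- sample(4:12, 1)
    ne <- sample(0:(n + 2), 1)
    edges <- cbind(sample(n, ne, replace = TRUE), sample(n, ne, replace = TRUE))
    edges <- edges[edges[, 1] != edges[, 2], , drop = FALSE]
    triples <- lapply(seq_len(nrow(edges)), function(r) {
      c(edges[r, 1], edges[r, 2], 5, 0)
    })
    links <- make_links(n, triples)
    ours <- clusters(connectivity_graph(links, n))
    ref <- oracle_components(n, edges)
    expect_equal(ours[order(vapply(ours, min, numeric(1)))],
                 ref[order(vapply(ref, min, numeric(1)))])
  }
})

test_that("clusters classify as free, oligomer, beta-sheet or beta-barrel", {
  cyc <- make_links(6, lapply(1:6, function(k) c(k, k %% 6 + 1, 5, 0)))
  expect_equal(classify_cluster(1:6, cyc), "beta_barrel")
  path <- make_links(6, lapply(1:5, function(k) c(k, k + 1, 6, 0)))
  expect_equal(classify_cluster(1:6, path), "beta_sheet")
  phob <- make_links(3, list(c(1, 2, 0, 3), c(2, 3, 0, 2)))
  expect_equal(classify_cluster(1:3, phob), "oligomer")
  expect_equal(classify_cluster(4, phob), "free")
  # a 3-path is connected but below the sheet threshold
  p3 <- make_links(3, list(c(1, 2, 5, 0), c(2, 3, 5, 0)))
  expect_equal(classify_cluster(1:3, p3, sheet_min = 4), "oligomer")
  expect_equal(classify_cluster(1:3, p3, sheet_min = 3), "beta_sheet")
  # permutation invariance under peptide relabelling
  perm <- make_links(8, lapply(list(c(7, 2), c(2, 5), c(5, 1), c(1, 7)),
                               function(p) c(p[1], p[2], 5, 0)))
  expect_equal(classify_cluster(c(1, 2, 5, 7), perm), "beta_barrel")
})

test_that("scripted trajectories are reproduced frame-for-frame", {
  script <- list(
    # frame 1: all free
    list(),
    # frame 2: a hydrophobic oligomer forms
    list(list(members = c(1, 2, 3), class = "oligomer")),
    # frames 3-4: six strands close into a barrel
    list(list(members = 1:6, class = "barrel")),
    list(list(members = 1:6, class = "barrel"),
         list(members = c(7, 8, 9, 10), class = "sheet")),
    # frame 5: the barrel opens into a sheet
    list(list(members = 1:6, class = "sheet"),
         list(members = c(7, 8, 9, 10), class = "sheet"))
  )
  traj <- scripted_trajectory(12, script)
  rep <- kinetics_timeseries(traj)
  truth <- attr(traj, "ground_truth")
  for (f in seq_along(script)) {
    got <- rep$frames[[f]]
    got_nonfree <- Filter(function(cl) cl$class != "free", got)
    want <- truth[[f]]$clusters
    expect_equal(length(got_nonfree), length(want), info = paste("frame", f))
    for (w in want) {
      hit <- Filter(function(cl) identical(cl$members, w$members), got_nonfree)
      expect_equal(length(hit), 1, info = paste("frame", f))
      expect_equal(hit[[1]]$class, w$class, info = paste("frame", f))
    }
    # partition property: class counts sum to the number of peptides
    row <- rep$series[f, ]
    expect_equal(row$n_free + row$n_oligomeric + row$n_fibrillar, 12)
  }
  # the barrel-opening is logged as a single barrel-to-sheet transition
  tr <- rep$transitions
  b2s <- tr[tr$from_class == "beta_barrel" & tr$to_class == "beta_sheet", ]
  expect_equal(nrow(b2s), 1)
  expect_equal(b2s$frame, 5)
  # free-peptide count is monotone non-increasing on this aggregation script
  expect_true(all(diff(rep$series$n_free) <= 0))
  # an empty-script trajectory leaves every peptide free
  t0 <- scripted_trajectory(5, list(list(), list()))
  r0 <- kinetics_timeseries(t0)
  expect_true(all(r0$series$n_free == 5))
  expect_equal(nrow(r0$transitions), 0)
})

test_that("script validation rejects inconsistent cluster assignments", {
  expect_error(
    scripted_trajectory(6, list(list(list(members = c(1, 2, 3), class = "sheet"),
                                     list(members = c(3, 4), class = "sheet")))),
    "two clusters")
  expect_error(
    scripted_trajectory(3, list(list(list(members = c(2, 9), class = "sheet")))),
    "unknown")
})

test_that("hydrogen-bond half-time interpolates the sample log", {
  log <- data.frame(time = c(0, 10, 20, 30), n_hbonds = c(0, 2, 6, 8))
  expect_equal(hbond_halftime(log), 15)          # crosses 4 midway
  expect_true(is.na(hbond_halftime(data.frame(time = 0:3,
                                              n_hbonds = rep(0, 4)))))
})
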