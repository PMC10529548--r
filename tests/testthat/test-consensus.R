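test_that("pileup counts equal a brute-force recount", {
  ref <- c(mt = random_seq(300, seed = 51))
  idx <- build_index(ref, k = 13)
  reads <- simulate_reads(ref, read_sim_config(8, seq_error = 0.01,
                                               seed = 52))$reads
  aln <- map_reads(reads, idx, 0.10)
  pile <- build_pileup(aln, reads, ref)
  expect_equal(pile$depth, pile$A + pile$C + pile$G + pile$T)
  expect_equal(nrow(pile), 300L)

  # recount by laying reads out by hand
  counts <- matrix(0L, 4, 300, dimnames = list(c("A", "C", "G", "T"), NULL))
  joined <- dplyr::inner_join(aln, reads, by = "read_id")
  for (i in seq_len(nrow(joined))) {
    b <- joined$bases[i]
    if (joined$strand[i] == "-") b <- rc(b)
    v <- strsplit(b, "")[[1]]
    for (j in seq_along(v)) {
      if (v[j] %in% rownames(counts)) {
        counts[v[j], joined$start[i] + j] <- counts[v[j], joined$start[i] + j] + 1L
      }
    }
  }
  expect_equal(pile$A, unname(counts["A", ]))
  expect_equal(pile$T, unname(counts["T", ]))

  empty <- build_pileup(aln[0, ], reads, ref)
  expect_true(all(empty$depth == 0))
  bad <- aln[1, ]; bad$start <- 290L
  expect_error(build_pileup(bad, reads, ref), "bounds")
})

test_that("majority-rule calling applies threshold, depth and fill rules", {
  ref <- c(r = "AAAA")
  mk_pile <- function(A, C, G, T) {
    tibble::tibble(ref_id = "r", pos = 0:3, A = A, C = C, G = G, T = T,
                   depth = A + C + G + T)
  }
  # columns: A:3,G:1 | A:3,G:1 | depth 2 | depth 0
  pile <- mk_pile(A = c(3L, 3L, 1L, 0L), C = 0L, G = c(1L, 1L, 1L, 0L),
                  T = 0L)
  expect_equal(unname(call_consensus(pile, ref, consensus_config(0.5, 0, FALSE))),
               "AANN")  # 0.75 >= 0.5 called; depth-0 site N without fill
  expect_equal(substr(unname(call_consensus(pile, ref,
                                            consensus_config(0.9, 0, FALSE))), 1, 1),
               "N")  # 0.75 < 0.9
  expect_equal(substr(unname(call_consensus(pile, ref,
                                            consensus_config(0.5, 3, FALSE))), 3, 3),
               "N")  # depth 2 below min_depth 3
  expect_equal(substr(unname(call_consensus(pile, ref,
                                            consensus_config(0.5, 0, TRUE))), 4, 4),
               "A")  # depth 0 filled from reference

  # exact-threshold boundary: 17/20 = 0.85 is called under >=
  pile85 <- tibble::tibble(ref_id = "r", pos = 0L, A = 17L, C = 3L, G = 0L,
                           T = 0L, depth = 20L)
  expect_equal(unname(call_consensus(pile85, c(r = "C"),
                                     consensus_config(0.85, 10, FALSE))), "A")
  # tie between most frequent bases yields N
  tie <- tibble::tibble(ref_id = "r", pos = 0L, A = 2L, C = 2L, G = 0L,
                        T = 0L, depth = 4L)
  expect_equal(unname(call_consensus(tie, c(r = "G"),
                                     consensus_config(0.5, 0, FALSE))), "N")
})

test_that("strict-majority pileups are called at every column", {
  set.seed(53)
  n <- 50
  counts <- t(vapply(seq_len(n), function(i) {
    x <- sample(0:5, 4, replace = TRUE)
    x[sample(4, 1)] <- sum(x) + 1L  # strict majority in every column
    x
  }, integer(4)))
  pile <- tibble::tibble(ref_id = "r", pos = 0:(n - 1),
                         A = counts[, 1], C = counts[, 2], G = counts[, 3],
                         T = counts[, 4], depth = rowSums(counts))
  out <- call_consensus(pile, c(r = strrep("A", n)),
                        consensus_config(0.5, 0, FALSE))
  expect_false(grepl("N", unname(out)))
})

test_that("iterative refinement converges and recovers a divergent source", {
  truth <- simulate_reference(4000, seed = 54, id = "mt")
  sim <- simulate_reads(truth, read_sim_config(30, seq_error = 0, seed = 55))
  # reads simulated from the mapping reference itself: converges quickly and
  # the consensus agrees with it wherever there is depth
  res <- iterative_refine(sim$reads, truth)
  expect_true(any(res$log$converged))
  expect_lte(nrow(res$log), 10L)
  fin <- strsplit(unname(res$consensus), "")[[1]]
  tv <- strsplit(unname(truth), "")[[1]]
  called <- fin != "N"
  expect_gte(mean(fin[called] == tv[called]), 0.999)

  # starting reference 5% diverged: the final call still matches the read
  # source at essentially all called sites
  start_ref <- mutate_sequence(truth, 0.05, seed = 56)
  expect_gte(museomics:::.n_diff(start_ref, truth), 100)
  res2 <- iterative_refine(sim$reads, start_ref)
  chk <- consensus_vs_truth(res2$consensus, truth)
  expect_gte(chk$identity, 0.995)
  expect_gt(chk$called_frac, 0.9)

  # iteration cap respected when convergence has not yet been reached
  res3 <- iterative_refine(sim$reads, start_ref, max_iterations = 2L)
  expect_equal(nrow(res3$log), 2L)
  expect_false(any(res3$log$converged))

  expect_error(iterative_refine(sim$reads,
                                simulate_reference(4000, gc = 0.99, seed = 57)),
               "no seed alignment")
})

test_that("final stringent call enforces the depth-10 and 85% rules", {
  truth <- simulate_reference(2000, seed = 58, id = "mt")
  sim <- simulate_reads(truth, read_sim_config(50, seq_error = 0, seed = 59))
  fin <- final_stringent_call(sim$reads, truth)
  fv <- strsplit(unname(fin$consensus), "")[[1]]
  # high-coverage error-free data: no N wherever depth >= 10
  deep <- fin$pileup$depth >= 10
  expect_true(all(fv[deep] != "N"))
  expect_true(all(fv[fin$pileup$depth < 10] == "N"))
  agree <- fv[deep] == strsplit(unname(truth), "")[[1]][deep]
  expect_true(all(agree))
})

test_that("region extraction finds maximal runs above the depth threshold", {
  depths <- c(0, 0, 3, 4, 5, 2, 3, 3)
  reg <- extract_regions(depths, min_depth = 3)
  expect_equal(reg$start, c(2L, 6L))
  expect_equal(reg$end, c(5L, 8L))
  expect_equal(reg$mean_depth, c(4, 3))
  expect_equal(nrow(extract_regions(rep(0, 10), 3)), 0L)
  all_deep <- extract_regions(rep(5, 10), 3)
  expect_equal(nrow(all_deep), 1L)
  expect_equal(c(all_deep$start, all_deep$end), c(0L, 10L))
  expect_equal(nrow(extract_regions(depths, 3, min_length = 3)), 1L)

  # linear-scan oracle on random depth vectors
  set.seed(60)
  for (i in 1:20) {
    d <- rpois(200, 2)
    reg <- extract_regions(d, 3)
    member <- rep(FALSE, 200)
    for (r in seq_len(nrow(reg))) {
      member[(reg$start[r] + 1):reg$end[r]] <- TRUE
    }
    expect_equal(member, d >= 3)
    # maximality: every region is flanked by below-threshold positions
    for (r in seq_len(nrow(reg))) {
      if (reg$start[r] > 0) expect_lt(d[reg$start[r]], 3)
      if (reg$end[r] < 200) expect_lt(d[reg$end[r] + 1], 3)
    }
  }
})
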