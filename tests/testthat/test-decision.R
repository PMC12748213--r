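test_that("self-consistency votes follow the majority-fraction formula", {
  j3 <- mock_judge(script = c("sufficient", "sufficient", "sufficient"))
  v <- run_votes("q", "ctx", j3)
  expect_identical(v$decision, "sufficient")
  expect_equal(v$c_internal, 1.0)
  j21 <- mock_judge(script = c("sufficient", "insufficient", "sufficient"))
  v21 <- run_votes("q", "ctx", j21)
  expect_identical(v21$decision, "sufficient")
  expect_equal(v21$c_internal, 2 / 3)
  j12 <- mock_judge(script = c("insufficient", "sufficient", "insufficient"))
  v12 <- run_votes("q", "ctx", j12)
  expect_identical(v12$decision, "insufficient")
  expect_equal(v12$c_internal, 2 / 3)
  expect_error(run_votes("q", "ctx", j3, n = 2), "odd|%%")
})

test_that("majority confidence over all 8 three-vote patterns", {
  # exhaustive oracle: every {suff, insuff}^3 pattern
  pats <- expand.grid(v1 = c("sufficient", "insufficient"),
                      v2 = c("sufficient", "insufficient"),
                      v3 = c("sufficient", "insufficient"),
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(pats))) {
    votes <- unlist(pats[i, ])
    v <- run_votes("q", "ctx", mock_judge(script = votes))
    ns <- sum(votes == "sufficient")
    expect_equal(v$c_internal, max(ns, 3 - ns) / 3)
    expect_gte(v$c_internal, 0.5)
    expect_identical(v$c_internal == 1, ns %in% c(0L, 3L))
    expect_identical(v$decision,
                     if (ns >= 2) "sufficient" else "insufficient")
  }
})

test_that("context metrics compute coverage, density, relevance", {
  kg <- clinic_graph()
  emb <- mock_embedder()
  linked <- list(list(entity_id = "d_cirr", confidence = 1),
                 list(entity_id = "d_hcc", confidence = 1))
  q <- structure(list(anchors = "d_cirr", relation_filter = character(0),
                      direction = "out", intent = "fact", signature = "x"),
                 class = "graph_query")
  ctx <- execute_query(kg, q, search_strategy("BFS", 2L))
  m <- compute_metrics("What about cirrhosis?", ctx, linked, emb)
  expect_equal(m$coverage, 1.0)  # both linked entities in the 2-hop ball
  expect_identical(m$n_nodes, length(ctx$node_ids))
  expect_gte(m$s_sem, 0); expect_lte(m$s_sem, 1)
  # empty context: all-zero metrics
  m0 <- compute_metrics("q", NULL, linked, emb)
  expect_identical(m0$n_nodes, 0L)
  expect_equal(overall_score(m0), 0)
  # density is the arithmetic mean of attribute counts
  md <- context_metrics(coverage = 1, n_nodes = 4, density = mean(c(2, 2, 4, 4)),
                        s_sem = 0.5)
  expect_equal(md$density, 3.0)
})

test_that("the overall score is the exact weighted sum", {
  cfg <- default_config()$decision
  m1 <- context_metrics(1, 0, 0, s_sem = 1, config = cfg)
  expect_equal(overall_score(m1, cfg), 0.4)
  m2 <- context_metrics(1, cfg$ref_nodes, 0, s_sem = 0, config = cfg)
  expect_equal(overall_score(m2, cfg), 0.3)
  m3 <- context_metrics(1, cfg$ref_nodes, cfg$ref_density, s_sem = 1,
                        config = cfg)
  expect_equal(overall_score(m3, cfg), 1.0)
  bad <- cfg; bad$w_sem <- 0.9
  expect_error(overall_score(m1, bad), "configuration error")
})

test_that("score is monotone in each component and stays in [0, 1]", {
  cfg <- default_config()$decision
  grid <- seq(0, 1, by = 0.25)
  for (s in grid) {
    for (nn in grid) {
      for (dd in grid) {
        m <- context_metrics(1, nn * cfg$ref_nodes, dd * cfg$ref_density,
                             s_sem = s, config = cfg)
        sc <- overall_score(m, cfg)
        expect_gte(sc, 0); expect_lte(sc, 1)
        m_up <- context_metrics(1, nn * cfg$ref_nodes, dd * cfg$ref_density,
                                s_sem = min(1, s + 0.25), config = cfg)
        expect_gte(overall_score(m_up, cfg), sc)
      }
    }
  }
})

test_that("adjudication follows the full truth table", {
  cfg <- default_config()$decision
  vs <- function(dec, ci = 2 / 3) {
    structure(list(model_id = "m", votes = character(0), decision = dec,
                   c_internal = ci), class = "vote_record")
  }
  S <- vs("sufficient", 1); I <- vs("insufficient", 2 / 3)
  scores <- c(low = 0.2, mid = 0.55, high = 0.9)
  # agreement: decision stands whatever the score
  for (sc in scores) {
    a <- adjudicate(S, vs("sufficient", 2 / 3), sc, cfg)
    expect_identical(a$action, "USE_CURRENT")
    expect_equal(a$c_decision, mean(c(1, 2 / 3)))
    b <- adjudicate(I, vs("insufficient", 1), sc, cfg)
    expect_identical(b$action, "RETRY_SEARCH")
  }
  # disagreement: the score arbitrates
  expect_identical(adjudicate(S, I, scores["high"], cfg)$action,
                   "USE_CURRENT")
  expect_identical(adjudicate(S, I, scores["low"], cfg)$action,
                   "RETRY_SEARCH")
  # between thresholds: conservative insufficient
  mid <- adjudicate(S, I, scores["mid"], cfg)
  expect_identical(mid$action, "RETRY_SEARCH")
  expect_match(mid$rationale, "conservative")
  # score-adjudicated confidence lies in [0.5, 1]
  for (sc in c(0, 0.3, 0.55, 0.71, 1)) {
    cd <- adjudicate(S, I, sc, cfg)$c_decision
    expect_gte(cd, 0.5); expect_lte(cd, 1)
  }
  # purity: identical inputs, identical result
  expect_identical(adjudicate(S, I, 0.9, cfg), adjudicate(S, I, 0.9, cfg))
})

test_that("the optimizer applies exactly the first triggered rule", {
  cfg <- default_config()$decision
  s0 <- search_strategy("BFS", 2L, node_limit = 50L)
  # rule 1: low coverage, depth below max
  m1 <- context_metrics(0.2, 10, 5, s_sem = 0.9, config = cfg)
  o1 <- optimize_strategy(s0, m1, cfg)
  expect_identical(o1$strategy$k, 3L)
  expect_identical(o1$trace$rule, "coverage_low_increase_depth")
  expect_identical(o1$strategy$method, s0$method)  # single-field change
  # rule 2 first branch: low relevance, no switch yet
  m2 <- context_metrics(0.9, 10, 5, s_sem = 0.1, config = cfg)
  o2 <- optimize_strategy(s0, m2, cfg)
  expect_identical(o2$strategy$method, "DFS")
  expect_true(o2$strategy$switched_flag)
  # rule 2 second branch: already switched -> node limit doubles
  o2b <- optimize_strategy(o2$strategy, m2, cfg)
  expect_identical(o2b$strategy$node_limit, 100L)
  expect_identical(o2b$strategy$method, "DFS")
  # rule 3: only density low
  m3 <- context_metrics(0.9, 10, 0.3, s_sem = 0.9, config = cfg)
  o3 <- optimize_strategy(s0, m3, cfg)
  expect_identical(o3$strategy$node_limit, 100L)
  expect_identical(o3$trace$rule, "density_low_increase_limit")
  # nothing triggers: no-op trace
  m4 <- context_metrics(0.9, 20, 5, s_sem = 0.9, config = cfg)
  o4 <- optimize_strategy(s0, m4, cfg)
  expect_identical(o4$trace$rule, "none")
  expect_identical(o4$strategy, s0)
})

test_that("the optimizer never exceeds its caps and is deterministic", {
  cfg <- default_config()$decision
  s <- search_strategy("BFS", 4L, node_limit = 150L, k_max = 4L,
                       limit_max = 200L)
  # coverage low but depth at max -> falls through to later rules
  m <- context_metrics(0.1, 1, 0.1, s_sem = 0.1, config = cfg)
  for (i in 1:5) {
    out <- optimize_strategy(s, m, cfg, iteration = i)
    s <- out$strategy
    expect_lte(s$k, 4L)
    expect_lte(s$node_limit, 200L)
  }
  s1 <- search_strategy("DFS", 3L)
  m1 <- context_metrics(0.2, 5, 1, s_sem = 0.2, config = cfg)
  expect_identical(optimize_strategy(s1, m1, cfg),
                   optimize_strategy(s1, m1, cfg))
})
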