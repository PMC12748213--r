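#' Default configuration
#'
#' One nested list collecting every tunable weight and threshold, mirroring
#' a YAML config file (see [read_config()]):
#'
#' * `decision`: score weights `w_sem = 0.4`, `w_cov = 0.3`, `w_den = 0.3`
#'   (must sum to 1); arbitration thresholds `tau_high = 0.70`,
#'   `tau_low = 0.40`; optimizer metric thresholds `tau_coverage = 0.5`,
#'   `tau_semantic = 0.5`, `tau_density = 0.4`; normalization references
#'   `ref_nodes = 20`, `ref_density = 5`; votes per judge `n_votes = 3`.
#' * `confidence`: final-confidence weights `w_cypher = 0.3`,
#'   `w_decision = 0.3`, `w_coverage = 0.2`, `w_entity = 0.2` (sum to 1);
#'   per-extra-iteration penalty `iteration_penalty = 0.05`.
#' * `workflow`: `max_iterations = 3` refinement iterations;
#'   `temperature = 0.1` for real generators (ignored by mocks).
#' * `linker`: `threshold = 0.8`, `w_fuzzy = 0.5`, `w_semantic = 0.5`,
#'   `disambiguation_margin = 0.05`.
#' * `providers`: `backend = "mock"`, `judge_overlap_threshold = 0.3`,
#'   `embed_dim = 64`, `seed = 0`.
#'
#' @return The configuration list.
#' @export
default_config <- function() {
  list(
    decision = list(w_sem = 0.4, w_cov = 0.3, w_den = 0.3,
                    tau_high = 0.70, tau_low = 0.40,
                    tau_coverage = 0.5, tau_semantic = 0.5,
                    tau_density = 0.4,
                    ref_nodes = 20, ref_density = 5, n_votes = 3L),
    confidence = list(w_cypher = 0.3, w_decision = 0.3, w_coverage = 0.2,
                      w_entity = 0.2, iteration_penalty = 0.05),
    workflow = list(max_iterations = 3L, temperature = 0.1),
    linker = list(threshold = 0.8, w_fuzzy = 0.5, w_semantic = 0.5,
                  disambiguation_margin = 0.05),
    providers = list(backend = "mock", judge_overlap_threshold = 0.3,
                     embed_dim = 64L, seed = 0L)
  )
}

#' Read a configuration file
#'
#' YAML blocks override the corresponding [default_config()] entries;
#' anything unspecified keeps its default.
#'
#' @param path YAML path.
#' @return Configuration list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  for (block in names(user)) {
    for (key in names(user[[block]])) {
      cfg[[block]][[key]] <- user[[block]][[key]]
    }
  }
  cfg
}

#' Self-consistency voting
#'
#' Asks one judge for `n` independent votes on whether the retrieved
#' context suffices to answer the question. The majority is the judge's
#' preliminary decision and the majority fraction
#' `max(N_sufficient, N_insufficient) / N_total` is its internal
#' consistency score (with the default `n = 3`, always 2/3 or 1). A judge
#' call that errors is counted as an insufficient vote and logged.
#'
#' @param question The question.
#' @param context_text Serialized retrieved context.
#' @param judge A judge contract.
#' @param n Number of votes (odd; default 3).
#' @param seed Base seed; vote `i` uses `seed + i`.
#' @return A `vote_record`: `model_id`, `votes`, `decision`
#'   (`"sufficient"`/`"insufficient"`), `c_internal`.
#' @export
run_votes <- function(question, context_text, judge, n = 3L, seed = 0L) {
  stopifnot(n %% 2 == 1)
  votes <- character(n)
  for (i in seq_len(n)) {
    votes[i] <- tryCatch(judge$vote(question, context_text, seed + i),
                         error = function(e) {
                           warning("judge call failed; counting vote as insufficient",
                                   call. = FALSE)
                           "insufficient"
                         })
  }
  n_suff <- sum(votes == "sufficient")
  n_insuff <- n - n_suff
  structure(list(model_id = judge$kind %||% "judge",
                 votes = votes,
                 decision = if (n_suff > n_insuff) "sufficient" else "insufficient",
                 c_internal = max(n_suff, n_insuff) / n),
            class = "vote_record")
}

#' Objective context metrics
#'
#' Computes the evaluation module's external metrics for a retrieved
#' context: coverage (fraction of linked entities present among the
#' context nodes; degenerate 1.0 when nothing was linked), node count,
#' information density (mean attribute count per node), and semantic
#' relevance (clamped cosine between the question embedding and the
#' serialized-context embedding). Node count and density are normalized by
#' fixed references with clipping: `Norm(x) = min(x / x_ref, 1)`.
#'
#' @param question The question.
#' @param context A `retrieved_context` (see [execute_query()]), or `NULL`
#'   /empty for the all-zero metrics.
#' @param linked_entities Linked entities used for coverage.
#' @param embedder Embedder contract.
#' @param config `decision` config block (references).
#' @return A `context_metrics` list: `coverage`, `n_nodes`, `density`,
#'   `s_sem`, `norm_nodes`, `norm_density`.
#' @export
compute_metrics <- function(question, context, linked_entities,
                            embedder = mock_embedder(),
                            config = default_config()$decision) {
  if (is.null(context) || length(context$node_ids) == 0) {
    return(context_metrics(coverage = 0, n_nodes = 0L, density = 0,
                           s_sem = 0, config = config))
  }
  ids <- vapply(linked_entities, function(l) l$entity_id, "")
  ids <- ids[!is.na(ids)]
  coverage <- if (length(ids) == 0) 1 else mean(ids %in% context$node_ids)
  n_nodes <- length(context$node_ids)
  density <- mean(vapply(context$node_attr_counts, identity, numeric(1)))
  s_sem <- if (!nzchar(context$text)) 0 else {
    max(0, cosine_similarity(embedder$embed(question),
                             embedder$embed(context$text)))
  }
  context_metrics(coverage, n_nodes, density, s_sem, config)
}

#' Construct context metrics directly
#'
#' @param coverage Coverage fraction in `[0, 1]`.
#' @param n_nodes Retrieved node count.
#' @param density Mean attributes per node.
#' @param s_sem Semantic relevance in `[0, 1]`.
#' @param config `decision` config block supplying normalization
#'   references.
#' @return A `context_metrics` list.
#' @export
context_metrics <- function(coverage, n_nodes, density, s_sem,
                            config = default_config()$decision) {
  structure(list(coverage = coverage, n_nodes = as.integer(n_nodes),
                 density = density, s_sem = s_sem,
                 norm_nodes = min(n_nodes / config$ref_nodes, 1),
                 norm_density = min(density / config$ref_density, 1)),
            class = "context_metrics")
}

#' Weighted overall context score
#'
#' `Score = w_sem * S_sem + w_cov * Norm(N_nodes) + w_den * Norm(D_avg)`
#' with default weights 0.4 / 0.3 / 0.3 — the emphasis is on semantic
#' relevance. Weights must sum to 1, so the score stays in `[0, 1]` for
#' components in `[0, 1]`.
#'
#' @param metrics A [context_metrics()].
#' @param config `decision` config block (weights).
#' @return Score in `[0, 1]`.
#' @export
overall_score <- function(metrics, config = default_config()$decision) {
  w <- c(config$w_sem, config$w_cov, config$w_den)
  if (abs(sum(w) - 1) > 1e-9) {
    stop("configuration error: score weights must sum to 1", call. = FALSE)
  }
  config$w_sem * metrics$s_sem +
    config$w_cov * metrics$norm_nodes +
    config$w_den * metrics$norm_density
}

#' Arbitrate the two judges' decisions
#'
#' When the two vote records agree, their shared decision stands and the
#' decision confidence is the mean of the two internal-consistency scores.
#' On disagreement the objective score arbitrates: above `tau_high` the
#' context is deemed sufficient, below `tau_low` insufficient, and in
#' between the conservative reading (insufficient) is taken and logged.
#' Score-adjudicated confidence is the score's distance from the
#' between-thresholds midpoint, scaled into `[0.5, 1]`.
#'
#' @param vote_primary,vote_secondary [run_votes()] records.
#' @param score_overall The [overall_score()].
#' @param config `decision` config block.
#' @return A `decision_result`: `action` (`"USE_CURRENT"` or
#'   `"RETRY_SEARCH"`), `decision`, `c_decision`, `score_overall`,
#'   `votes`, `rationale`.
#' @export
adjudicate <- function(vote_primary, vote_secondary, score_overall,
                       config = default_config()$decision) {
  tau_high <- config$tau_high; tau_low <- config$tau_low
  stopifnot(tau_low < tau_high)
  if (identical(vote_primary$decision, vote_secondary$decision)) {
    decision <- vote_primary$decision
    c_decision <- mean(c(vote_primary$c_internal, vote_secondary$c_internal))
    rationale <- sprintf("judges agree: %s", decision)
  } else {
    mid <- (tau_high + tau_low) / 2
    half <- (tau_high - tau_low) / 2
    if (score_overall > tau_high) {
      decision <- "sufficient"
      rationale <- sprintf("judges disagree; score %.3f > tau_high %.2f",
                           score_overall, tau_high)
    } else if (score_overall < tau_low) {
      decision <- "insufficient"
      rationale <- sprintf("judges disagree; score %.3f < tau_low %.2f",
                           score_overall, tau_low)
    } else {
      decision <- "insufficient"
      rationale <- sprintf(
        "judges disagree; score %.3f between thresholds - conservative insufficient",
        score_overall)
    }
    c_decision <- 0.5 + 0.5 * min(1, abs(score_overall - mid) / half)
  }
  structure(list(
    action = if (decision == "sufficient") "USE_CURRENT" else "RETRY_SEARCH",
    decision = decision,
    c_decision = c_decision,
    score_overall = score_overall,
    votes = list(primary = vote_primary, secondary = vote_secondary),
    rationale = rationale
  ), class = "decision_result")
}

#' Deterministic strategy optimizer
#'
#' After an insufficient verdict, exactly one rule of the decision tree is
#' applied — the first whose trigger fires, so each refinement changes one
#' strategy field family and the change is attributable:
#'
#' 1. coverage below `tau_coverage` and depth below its maximum ->
#'    increase the depth by 1;
#' 2. semantic relevance below `tau_semantic` -> switch BFS <-> DFS if no
#'    switch happened yet, else double the node limit (capped);
#' 3. density below `tau_density` -> double the node limit (capped).
#'
#' When no rule triggers, the strategy is returned unchanged with a no-op
#' trace (the workflow then answers from the current context).
#'
#' @param strategy A [search_strategy()].
#' @param metrics A [context_metrics()].
#' @param config `decision` config block (thresholds).
#' @param iteration Iteration index recorded in the trace.
#' @return List with the new `strategy` and a `trace`
#'   (`list(iteration, rule, field, old, new)`).
#' @export
optimize_strategy <- function(strategy, metrics,
                              config = default_config()$decision,
                              iteration = 1L) {
  trace <- list(iteration = iteration, rule = "none", field = NA_character_,
                old = NA, new = NA)
  s <- strategy
  if (metrics$coverage < config$tau_coverage && strategy$k < strategy$k_max) {
    s$k <- strategy$k + 1L
    trace$rule <- "coverage_low_increase_depth"
    trace$field <- "k"; trace$old <- strategy$k; trace$new <- s$k
  } else if (metrics$s_sem < config$tau_semantic) {
    if (!strategy$switched_flag) {
      s$method <- if (strategy$method == "BFS") "DFS" else "BFS"
      s$switched_flag <- TRUE
      trace$rule <- "semantic_low_switch_method"
      trace$field <- "method"; trace$old <- strategy$method; trace$new <- s$method
    } else {
      s$node_limit <- min(strategy$node_limit * 2L, strategy$limit_max)
      trace$rule <- "semantic_low_increase_limit"
      trace$field <- "node_limit"; trace$old <- strategy$node_limit
      trace$new <- s$node_limit
    }
  } else if (metrics$density < config$tau_density) {
    s$node_limit <- min(strategy$node_limit * 2L, strategy$limit_max)
    trace$rule <- "density_low_increase_limit"
    trace$field <- "node_limit"; trace$old <- strategy$node_limit
    trace$new <- s$node_limit
  }
  list(strategy = s, trace = trace)
}
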