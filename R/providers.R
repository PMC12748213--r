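#' @name providers
#' @title Provider contracts and seeded mock implementations
#'
#' @description
#' The framework needs three external capabilities: free-text generation,
#' context-sufficiency judging, and text embedding. Each is abstracted
#' behind a small contract (a list of functions) so the entire workflow
#' runs offline and deterministically with the packaged mocks, and a real
#' LLM / embedding backend can be dropped in without touching any
#' workflow code path.
#'
#' * Generator: `generate(prompt, temperature = 0.1, seed = 0)` -> text.
#' * Judge: `vote(question, context_text, seed = 0)` -> `"sufficient"` or
#'   `"insufficient"`.
#' * Embedder: `embed(text)` -> fixed-length numeric vector, deterministic
#'   in the text (identical strings give identical vectors).
NULL

# Deterministic 32-bit-safe string hash (FNV-1a variant over UTF-8 bytes,
# kept in double precision well below 2^53). No dependence on R's or the
# OS's hash randomization.
string_hash <- function(x, seed = 0) {
  bytes <- as.integer(charToRaw(enc2utf8(x)))
  h <- 2166136261 + seed * 97
  for (b in bytes) {
    h <- (h %% 8388608) * 16777619 + b   # keep magnitude bounded
  }
  h %% 2147483647
}

tokenize <- function(text) {
  toks <- unlist(strsplit(tolower(text), "[^a-z0-9]+"))
  toks[nzchar(toks)]
}

stopwords <- function() {
  c("a", "an", "and", "are", "be", "by", "can", "do", "does", "for", "how",
    "i", "in", "is", "it", "me", "my", "of", "off", "on", "or", "s", "should",
    "take", "tell", "the", "to", "what", "which", "why", "with", "you")
}

content_tokens <- function(text) setdiff(tokenize(text), stopwords())

#' Seeded mock embedder
#'
#' Embeds text as seeded hashed token counts: each token is hashed to one
#' of `dim` buckets with a deterministic sign, and the bucket counts form
#' the vector. Identical strings therefore embed identically (cosine 1),
#' and texts with disjoint token sets are (near-)orthogonal.
#'
#' @param dim Vector length (default 64).
#' @param seed Hash seed; different seeds give different, equally valid
#'   embedding spaces.
#' @return An embedder contract: `list(embed = function(text), dim =)`.
#' @export
mock_embedder <- function(dim = 64L, seed = 0L) {
  force(dim); force(seed)
  list(
    kind = "mock_embedder",
    dim = dim,
    embed = function(text) {
      v <- numeric(dim)
      for (tok in tokenize(text)) {
        h <- string_hash(tok, seed)
        idx <- (h %% dim) + 1L
        sgn <- if ((h %/% dim) %% 2 == 0) 1 else -1
        v[idx] <- v[idx] + sgn
      }
      v
    }
  )
}

#' Cosine similarity
#'
#' @param a,b Numeric vectors of equal length.
#' @return Cosine of the angle between `a` and `b`; 0 (with a warning)
#'   when either vector has zero norm.
#' @export
cosine_similarity <- function(a, b) {
  na <- sqrt(sum(a * a)); nb <- sqrt(sum(b * b))
  if (na == 0 || nb == 0) {
    warning("zero-norm vector in cosine similarity; returning 0",
            call. = FALSE)
    return(0)
  }
  sum(a * b) / (na * nb)
}

#' Seeded mock judge
#'
#' Votes "sufficient" when the fraction of the question's content tokens
#' that also occur in the context text reaches `overlap_threshold`.
#' `mode` overrides the rule for testing the workflow's branches:
#' `"sufficient"` / `"insufficient"` force a constant vote, and
#' `script` replays a fixed vote sequence (recycled).
#'
#' @param overlap_threshold Fraction in `[0, 1]` (default 0.3).
#' @param mode `"overlap"` (default), `"sufficient"`, or `"insufficient"`.
#' @param script Optional character vector of votes to replay in order.
#' @return A judge contract: `list(vote = function(question, context_text,
#'   seed))`.
#' @export
mock_judge <- function(overlap_threshold = 0.3, mode = "overlap",
                       script = NULL) {
  force(overlap_threshold); force(mode); force(script)
  pos <- 0L
  list(
    kind = "mock_judge",
    mode = mode,
    vote = function(question, context_text, seed = 0L) {
      if (!is.null(script)) {
        pos <<- pos + 1L
        return(script[((pos - 1L) %% length(script)) + 1L])
      }
      if (mode == "sufficient") return("sufficient")
      if (mode == "insufficient") return("insufficient")
      q <- content_tokens(question)
      if (length(q) == 0) return("insufficient")
      ctx <- tokenize(context_text)
      frac <- mean(q %in% ctx)
      if (frac >= overlap_threshold) "sufficient" else "insufficient"
    }
  )
}

#' Seeded mock generator
#'
#' A deterministic stand-in for an instruction-following language model.
#' Prompts are task-tagged JSON envelopes (the same contract a real
#' backend would receive); the mock dispatches on the tag:
#'
#' * `plan_query`: returns a structured graph-query payload built
#'   deterministically from the question's intent and linked entities.
#' * `synthesize`: returns an answer template citing every context fact
#'   anchor.
#' * `regenerate_questions`: returns templated question transforms of an
#'   answer (used by the answer-relevancy metric).
#' * `extract_statements`: splits an answer into its sentence statements.
#' * anything else: echoes a deterministic digest of the prompt.
#'
#' @param model_id Identifier recorded in payloads ("primary"/"secondary").
#' @param divergent If `TRUE` the planner payload drops the last relation
#'   type from its filter — a hook to construct dual-model disagreement in
#'   tests.
#' @return A generator contract:
#'   `list(generate = function(prompt, temperature, seed), model_id =)`.
#' @export
mock_generator <- function(model_id = "primary", divergent = FALSE) {
  force(model_id); force(divergent)
  list(
    kind = "mock_generator",
    model_id = model_id,
    generate = function(prompt, temperature = 0.1, seed = 0L) {
      req <- tryCatch(jsonlite::fromJSON(prompt, simplifyVector = FALSE),
                      error = function(e) NULL)
      task <- if (is.null(req)) "echo" else req$task %||% "echo"
      if (task == "plan_query") {
        rels <- as.character(unlist(req$relation_hint))
        if (divergent && length(rels) > 0) rels <- rels[-length(rels)]
        payload <- list(anchors = req$anchors, relations = as.list(rels),
                        direction = req$direction %||% "out",
                        intent = req$intent, model_id = model_id)
        return(as.character(jsonlite::toJSON(payload, auto_unbox = TRUE)))
      }
      if (task == "synthesize") {
        facts <- as.character(unlist(req$fact_lines))
        anchors <- regmatches(facts, regexpr("\\[F[0-9]+\\]", facts))
        body <- paste0("Based on the knowledge graph: ",
                       paste(sub("^\\[F[0-9]+\\] ", "", facts), " ",
                             anchors, collapse = " ", sep = ""))
        return(paste0("Q: ", req$question, "\n", body))
      }
      if (task == "regenerate_questions") {
        n <- req$n %||% 3
        toks <- content_tokens(req$answer %||% "")
        topic <- paste(utils::head(toks, 4), collapse = " ")
        templates <- c(paste0("What is known about ", topic, "?"),
                       paste0("Can you explain ", topic, "?"),
                       paste0("Which facts relate to ", topic, "?"),
                       paste0("Why is ", topic, " relevant?"),
                       paste0("How does ", topic, " apply?"))
        return(as.character(jsonlite::toJSON(
          as.list(templates[seq_len(min(n, length(templates)))]),
          auto_unbox = TRUE)))
      }
      if (task == "extract_statements") {
        sents <- trimws(split_sentences(req$answer %||% ""))
        return(as.character(jsonlite::toJSON(as.list(sents[nzchar(sents)]),
                                             auto_unbox = TRUE)))
      }
      paste0("mock(", model_id, ":", string_hash(prompt, seed), ")")
    }
  )
}

#' Assemble a provider set
#'
#' Builds the five providers the workflow consumes: primary and secondary
#' generators, primary and secondary judges, and one embedder. With the
#' default mock backend everything is deterministic and offline. A real
#' backend would read credentials from the environment; configuring one
#' here without the corresponding implementation is an error surfaced to
#' the workflow (which falls back).
#'
#' @param config A list, typically the `providers` block of
#'   [default_config()]: `backend` (`"mock"`), `judge_overlap_threshold`,
#'   `embed_dim`, `seed`, plus optional test hooks `judge_mode` /
#'   `judge_script` applied to both judges.
#' @return A `provider_set` list: `generator_primary`,
#'   `generator_secondary`, `judge_primary`, `judge_secondary`, `embedder`.
#' @export
make_provider_set <- function(config = list()) {
  backend <- config$backend %||% "mock"
  if (backend != "mock") {
    stop("provider error: backend '", backend,
         "' is not available in this installation", call. = FALSE)
  }
  seed <- as.integer(config$seed %||% 0L)
  thr <- config$judge_overlap_threshold %||% 0.3
  mode <- config$judge_mode %||% "overlap"
  script <- config$judge_script
  structure(list(
    generator_primary = mock_generator("primary"),
    generator_secondary = mock_generator("secondary",
                                         divergent = isTRUE(config$divergent_secondary)),
    judge_primary = mock_judge(thr, mode, script),
    judge_secondary = mock_judge(thr, mode, script),
    embedder = mock_embedder(config$embed_dim %||% 64L, seed)
  ), class = "provider_set")
}
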