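# Prompted event segmentation through an injected text-generation client.
# The client is any R function with signature
#   function(prompt, temperature, max_tokens, instance_index) -> completion
# so real API backends and the bundled deterministic mock share one contract.

prompt_header <- paste(
  "An event is an ongoing coherent situation.",
  "The following story needs to be copied and segmented into large events.",
  "Copy the following story word-for-word and start a new line whenever one",
  "event ends, and another begins. This is the story:")

prompt_footer <- paste(
  "This is a word-for-word copy of the same story that is segmented into",
  "large event units:")

#' Build the zero-shot segmentation prompt
#'
#' The instruction paragraph defines an event ("An event is an ongoing
#' coherent situation.") and asks for a word-for-word copy of the story with
#' a new line wherever one event ends; the narrative text is inserted after
#' "This is the story:" and the prompt closes by announcing the segmented
#' copy. The template is fixed; only the story text varies.
#'
#' @param narr A narrative.
#' @return A single prompt string.
#' @export
build_prompt <- function(narr) {
  stopifnot(inherits(narr, "eventseg_narrative"))
  paste0(prompt_header, "\n\n", narr$text, "\n\n", prompt_footer)
}

#' Model run configuration
#'
#' @param temperature Sampling temperature in `[0, 1]`. Backends that forbid
#'   an exact zero receive `temperature_floor` instead, but the condition is
#'   still labeled with the nominal temperature so conditions stay
#'   comparable across providers.
#' @param max_tokens Completion budget per request (default 4096, enough for
#'   a full segmented copy of a ~1500-word narrative).
#' @param n_instances Number of independent runs per narrative; each
#'   instance is treated like one participant (default 20).
#' @param provider_label,model_label Free-text labels recorded in outputs.
#' @param seed Optional seed, honored only by deterministic mock clients.
#' @param temperature_floor Lowest temperature the backend accepts.
#' @param max_retries Bounded retries per instance on client error.
#' @param min_fidelity Copy fidelity threshold for parsing (see
#'   [parse_segmented_copy()]).
#' @return A list of class `eventseg_model_config`.
#' @export
model_config <- function(temperature = 0, max_tokens = 4096L,
                         n_instances = 20L, provider_label = "mock",
                         model_label = "mock", seed = NULL,
                         temperature_floor = 0, max_retries = 2L,
                         min_fidelity = 0.95) {
  if (!is.numeric(temperature) || length(temperature) != 1L ||
      temperature < 0 || temperature > 1) {
    es_error("temperature must be a single value in [0, 1]",
             "eventseg_invalid_input")
  }
  if (!is_whole(n_instances) || n_instances < 1L) {
    es_error("n_instances must be a positive integer", "eventseg_invalid_input")
  }
  if (!is_whole(max_tokens) || max_tokens < 1L) {
    es_error("max_tokens must be a positive integer", "eventseg_invalid_input")
  }
  structure(
    list(temperature = temperature, max_tokens = as.integer(max_tokens),
         n_instances = as.integer(n_instances),
         provider_label = provider_label, model_label = model_label,
         seed = seed, temperature_floor = temperature_floor,
         max_retries = as.integer(max_retries), min_fidelity = min_fidelity),
    class = "eventseg_model_config"
  )
}

#' Run independent segmentation instances
#'
#' Sends the segmentation prompt to the client `n_instances` times, parsing
#' each completion back into boundary indices. Each run is labeled
#' `instance_00`, `instance_01`, ... with condition set to the nominal
#' temperature. Parse failures (degraded copies) are recorded per instance,
#' never silently dropped; client errors are retried with capped exponential
#' backoff and surfaced with the instance index if they persist.
#'
#' @param narr A narrative.
#' @param config An `eventseg_model_config`.
#' @param client Generation client function (see module header).
#' @return A list of class `eventseg_segmentation_run` with elements
#'   `responses` (successfully parsed `eventseg_response`s), `failures`
#'   (instance index + condition message), `completions` (raw completion
#'   text per instance, for audit) and `log` (one data.frame row per
#'   instance: status, fidelity, boundary count).
#' @export
run_instances <- function(narr, config, client) {
  stopifnot(inherits(narr, "eventseg_narrative"),
            inherits(config, "eventseg_model_config"),
            is.function(client))
  prompt <- build_prompt(narr)
  request_temp <- max(config$temperature, config$temperature_floor)
  condition <- as.character(config$temperature)

  responses <- list()
  failures <- list()
  completions <- character(config$n_instances)
  log_rows <- vector("list", config$n_instances)

  for (k in seq_len(config$n_instances) - 1L) {
    rater_id <- sprintf("instance_%02d", k)
    completion <- NULL
    last_err <- NULL
    for (attempt in 0:config$max_retries) {
      if (attempt > 0L) Sys.sleep(min(0.05 * 2^attempt, 1))
      completion <- tryCatch(
        client(prompt, temperature = request_temp,
               max_tokens = config$max_tokens, instance_index = k),
        error = function(e) {
          last_err <<- e
          NULL
        })
      if (!is.null(completion)) break
    }
    if (is.null(completion)) {
      failures[[length(failures) + 1L]] <- list(
        instance = k, stage = "client",
        message = sprintf("instance %d: client failed after %d attempts: %s",
                          k, config$max_retries + 1L,
                          conditionMessage(last_err)))
      log_rows[[k + 1L]] <- data.frame(
        instance = k, rater_id = rater_id, status = "client_error",
        fidelity = NA_real_, n_boundaries = NA_integer_,
        stringsAsFactors = FALSE)
      next
    }
    completions[k + 1L] <- completion
    parsed <- tryCatch(
      parse_segmented_copy(narr, completion,
                           min_fidelity = config$min_fidelity,
                           rater_id = rater_id, source = "llm",
                           condition = condition),
      eventseg_degraded_copy = function(e) e)
    if (inherits(parsed, "eventseg_response")) {
      responses[[length(responses) + 1L]] <- parsed
      log_rows[[k + 1L]] <- data.frame(
        instance = k, rater_id = rater_id, status = "ok",
        fidelity = attr(parsed, "fidelity"),
        n_boundaries = length(parsed$boundaries), stringsAsFactors = FALSE)
    } else {
      failures[[length(failures) + 1L]] <- list(
        instance = k, stage = "parse", message = conditionMessage(parsed))
      log_rows[[k + 1L]] <- data.frame(
        instance = k, rater_id = rater_id, status = "degraded_copy",
        fidelity = parsed$fidelity %||% NA_real_,
        n_boundaries = NA_integer_, stringsAsFactors = FALSE)
    }
  }

  if (length(responses) == 0L) {
    es_error(sprintf("all %d instances failed for narrative '%s'",
                     config$n_instances, narr$id), "eventseg_run_error")
  }
  structure(
    list(responses = responses, failures = failures,
         completions = completions, log = do.call(rbind, log_rows),
         condition = condition, narrative_id = narr$id, config = config),
    class = "eventseg_segmentation_run"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.eventseg_segmentation_run <- function(x, ...) {
  cat(sprintf("<segmentation run: narrative=%s condition=%s, %d ok / %d failed>\n",
              x$narrative_id, x$condition, length(x$responses),
              length(x$failures)))
  invisible(x)
}
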