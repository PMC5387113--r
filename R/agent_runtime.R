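#' Agent runtime: ticker and one-shot behaviours on a simulated clock
#'
#' A minimal single-threaded discrete-event scheduler plus message bus.
#' Agents declare behaviours at registration: *ticker* behaviours run
#' cyclically with a fixed period (continuous monitoring), *one-shot*
#' behaviours run once per triggering message (on-demand notification).
#' Concurrency is modelled, not real: the contract is the deterministic
#' event ordering below, which makes identical inputs produce byte-identical
#' event logs.
#'
#' Ordering rules:
#' * a ticker registered at time t0 with period p fires at t0, t0+p, t0+2p,
#'   ... (first firing at registration; flip with
#'   `first_tick_after_period = TRUE` to fire first at t0+p);
#' * simultaneous events are ordered by (agent registration order, behaviour
#'   index, scheduling sequence) ascending;
#' * messages between one sender-receiver pair are delivered in send order,
#'   exactly once; a message to an unregistered receiver is dead-lettered,
#'   never silently dropped and never fatal.
#'
#' @name agent_runtime
NULL

#' Declare an agent behaviour
#'
#' @param kind `"ticker"` (cyclic, requires `period`) or `"one_shot"`
#'   (fires once per delivered message, must not have a period).
#' @param action function `(runtime, agent_id, time, message)`; `message` is
#'   `NULL` for ticker firings.
#' @param period seconds between ticker firings, > 0.
#' @return a `behavior` list.
#' @export
behavior <- function(kind, action, period = NULL) {
  kind <- match.arg(kind, c("ticker", "one_shot"))
  stopifnot(is.function(action))
  if (kind == "ticker") {
    if (is.null(period) || !is.numeric(period) || period <= 0)
      stop("ticker behavior requires a period > 0", call. = FALSE)
  } else if (!is.null(period)) {
    stop("one_shot behavior must not have a period", call. = FALSE)
  }
  structure(list(kind = kind, action = action, period = period),
            class = "behavior")
}

#' @rdname agent_runtime
#' @export
AgentRuntime <- R6::R6Class("AgentRuntime",
  public = list(
    #' @field now current simulated time (seconds).
    now = 0,

    #' @description Create a runtime.
    #' @param start_time initial simulated time (seconds).
    #' @param delivery_latency simulated seconds between send and delivery
    #'   (default 0: same-tick handoff).
    #' @param first_tick_after_period if `TRUE`, tickers first fire one
    #'   period after registration instead of at registration time.
    initialize = function(start_time = 0, delivery_latency = 0,
                          first_tick_after_period = FALSE) {
      stopifnot(delivery_latency >= 0)
      self$now <- start_time
      private$latency <- delivery_latency
      private$tick_delay <- isTRUE(first_tick_after_period)
    },

    #' @description Register an agent and schedule its behaviours from the
    #'   current simulated time.
    #' @param agent_id unique string.
    #' @param behaviors non-empty list of [behavior()]s.
    #' @return the agent id, invisibly.
    register_agent = function(agent_id, behaviors) {
      if (agent_id %in% names(private$agents))
        stop("duplicate agent id '", agent_id, "'", call. = FALSE)
      if (length(behaviors) == 0)
        stop("agent '", agent_id, "' must have at least one behavior",
             call. = FALSE)
      stopifnot(all(vapply(behaviors, inherits, logical(1), "behavior")))
      order <- length(private$agents) + 1L
      private$agents[[agent_id]] <- list(order = order, behaviors = behaviors)
      for (bi in seq_along(behaviors)) {
        b <- behaviors[[bi]]
        if (b$kind == "ticker") {
          first <- self$now + if (private$tick_delay) b$period else 0
          private$push(first, order, bi, "tick", agent = agent_id)
        }
      }
      invisible(agent_id)
    },

    #' @description Send an asynchronous message.
    #' @param sender,receiver agent ids.
    #' @param performative `"inform"` or `"request"`.
    #' @param payload arbitrary payload (e.g. an [anomaly_event()]).
    #' @param at logical send time; defaults to the current simulated time.
    #'   Must not precede the current time.
    #' @return a receipt list with `status` `"scheduled"` or
    #'   `"dead_letter"`.
    send = function(sender, receiver, performative = "inform",
                    payload = NULL, at = NULL) {
      performative <- match.arg(performative, c("inform", "request"))
      at <- if (is.null(at)) self$now else as.numeric(at)
      if (at < self$now)
        stop("cannot send a message in the simulated past", call. = FALSE)
      msg <- list(sender = sender, receiver = receiver,
                  performative = performative, payload = payload,
                  sent_at = at)
      rcv <- private$agents[[receiver]]
      if (is.null(rcv)) {
        private$dead <- c(private$dead, list(msg))
        private$log_event(at, "dead_letter", sender,
                          info = paste0("unknown receiver '", receiver, "'"))
        return(list(status = "dead_letter", message = msg))
      }
      deliver_at <- at + private$latency
      one_shots <- which(vapply(rcv$behaviors, function(b) b$kind,
                                character(1)) == "one_shot")
      for (bi in one_shots)
        private$push(deliver_at, rcv$order, bi, "deliver",
                     agent = receiver, message = msg)
      list(status = "scheduled", deliver_at = deliver_at, message = msg)
    },

    #' @description Run the event loop up to and including `t_end`.
    #' @param t_end simulated end time (inclusive).
    #' @return the event log data frame, invisibly.
    run_until = function(t_end) {
      repeat {
        ev <- private$pop_min(t_end)
        if (is.null(ev)) break
        self$now <- ev$time
        ag <- private$agents[[ev$agent]]
        b <- ag$behaviors[[ev$behavior_index]]
        if (ev$kind == "tick") {
          private$log_event(ev$time, "tick", ev$agent,
                            behavior = ev$behavior_index)
          private$push(ev$time + b$period, ag$order, ev$behavior_index,
                       "tick", agent = ev$agent)
          b$action(self, ev$agent, ev$time, NULL)
        } else {
          private$log_event(ev$time, "deliver", ev$agent,
                            behavior = ev$behavior_index,
                            info = paste0("from ", ev$message$sender, " (",
                                          ev$message$performative, ")"))
          b$action(self, ev$agent, ev$time, ev$message)
        }
      }
      if (t_end > self$now) self$now <- t_end
      invisible(self$event_log())
    },

    #' @description The chronological event log.
    #' @return data frame with columns `time`, `kind`, `agent`, `behavior`,
    #'   `info`.
    event_log = function() {
      if (!length(private$log))
        return(data.frame(time = numeric(), kind = character(),
                          agent = character(), behavior = integer(),
                          info = character(), stringsAsFactors = FALSE))
      do.call(rbind, private$log)
    },

    #' @description Messages that could not be delivered.
    #' @return list of message records.
    dead_letters = function() private$dead,

    #' @description Export the event log as JSON-lines (one event per
    #'   line).
    #' @param path output path.
    #' @return `path`, invisibly.
    export_event_log = function(path) {
      log <- self$event_log()
      con <- file(path, "w")
      on.exit(close(con))
      for (i in seq_len(nrow(log)))
        writeLines(jsonlite::toJSON(as.list(log[i, ]), auto_unbox = TRUE),
                   con)
      invisible(path)
    }
  ),
  private = list(
    agents = list(),
    queue = list(),
    dead = list(),
    log = list(),
    latency = 0,
    tick_delay = FALSE,
    seq = 0L,

    push = function(time, agent_order, behavior_index, kind, agent,
                    message = NULL) {
      private$seq <- private$seq + 1L
      private$queue[[length(private$queue) + 1L]] <-
        list(time = time, order = agent_order,
             behavior_index = behavior_index, seq = private$seq,
             kind = kind, agent = agent, message = message)
    },

    # pop the earliest event with time <= t_end; ties broken by agent
    # registration order, then behavior index, then scheduling sequence
    pop_min = function(t_end) {
      if (!length(private$queue)) return(NULL)
      keys <- vapply(private$queue, function(e)
        c(e$time, e$order, e$behavior_index, e$seq), numeric(4))
      best <- do.call(order, as.data.frame(t(keys)))[1]
      ev <- private$queue[[best]]
      if (ev$time > t_end) return(NULL)
      private$queue[[best]] <- NULL
      ev
    },

    log_event = function(time, kind, agent, behavior = NA_integer_,
                         info = "") {
      private$log[[length(private$log) + 1L]] <-
        data.frame(time = time, kind = kind, agent = agent,
                   behavior = as.integer(behavior), info = info,
                   stringsAsFactors = FALSE)
    }
  )
)
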