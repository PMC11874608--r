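#!/usr/bin/env Rscript
# Thin command-line wrapper over the coordlearn package.
#
# Usage:
#   Rscript scripts/coordlearn.R simulate-study --seed 7 --out dir/
#   Rscript scripts/coordlearn.R score-trials --in dir/ --bandwidth 20 --out scores.csv
#   Rscript scripts/coordlearn.R run-protocol --coupling-rate 1.2 --seed 3 --out log.json
#   Rscript scripts/coordlearn.R run-staircase --observer-threshold 15 --seed 5 --out session.csv
#   Rscript scripts/coordlearn.R analyze-transfer --in means.csv --pattern ya_action --out transfer.json
#   Rscript scripts/coordlearn.R fit-learning --in curve.csv --out fit.json

suppressPackageStartupMessages({
  library(optparse)
  library(coordlearn)
})

argv <- commandArgs(trailingOnly = TRUE)
if (length(argv) < 1) {
  stop("usage: coordlearn.R <simulate-study|score-trials|run-protocol|",
       "run-staircase|analyze-transfer|fit-learning> [options]", call. = FALSE)
}
cmd <- argv[1]
rest <- argv[-1]

opt <- function(option_list) {
  parse_args(OptionParser(option_list = option_list), args = rest)
}
log_run <- function(o) {
  cfg <- o[setdiff(names(o), "help")]
  message(sprintf("[coordlearn %s] seed=%s config=%s version=%s", cmd,
                  if (is.null(o$seed)) "NA" else o$seed,
                  substr(digest_cfg(cfg), 1, 8),
                  as.character(utils::packageVersion("coordlearn"))))
}
digest_cfg <- function(x) {
  # small stable hash of the option list (hex of a running checksum)
  s <- paste(names(x), unlist(lapply(x, paste, collapse = ",")),
             collapse = ";")
  sprintf("%08x", sum(utf8ToInt(s) * seq_along(utf8ToInt(s))) %% .Machine$integer.max)
}

status <- tryCatch({
  switch(cmd,
    "simulate-study" = {
      o <- opt(list(
        make_option("--seed", type = "integer", default = 1L),
        make_option("--out", type = "character", default = "study_out"),
        make_option("--n-training", type = "integer", default = 2L,
                    dest = "n_training"),
        make_option("--duration", type = "double", default = 20)))
      log_run(o)
      des <- default_study_design(n_training = o$n_training)
      n_sessions <- max(des$session_index)
      sched <- list(
        YA = make_skill_schedule(n_sessions, coupling_max = 8, rate = 1),
        OA = make_skill_schedule(n_sessions, coupling_max = 8, rate = 0.4))
      ds <- simulate_study(des, sched, n_per_group = c(YA = 1, OA = 1),
                           osc = oscillator_params(duration = o$duration),
                           seed = o$seed)
      for (p in ds$participants) {
        trials <- unlist(p$sessions, recursive = FALSE, use.names = FALSE)
        meta <- data.frame(participant = p$id, group = p$group,
                           seed = o$seed)
        meta <- meta[rep(1, length(trials)), , drop = FALSE]
        write_trials(trials, file.path(o$out, p$id), meta = meta)
      }
      message("wrote ", length(ds$participants), " participants to ", o$out)
      0L
    },
    "score-trials" = {
      o <- opt(list(
        make_option("--in", type = "character", dest = "input"),
        make_option("--bandwidth", type = "double", default = 20),
        make_option("--out", type = "character", default = "scores.csv")))
      log_run(o)
      trials <- read_trials(o$input)
      utils::write.csv(score_trials(trials, bandwidth = o$bandwidth),
                       o$out, row.names = FALSE)
      message("wrote ", o$out)
      0L
    },
    "run-protocol" = {
      o <- opt(list(
        make_option("--coupling-rate", type = "double", default = 1,
                    dest = "rate"),
        make_option("--seed", type = "integer", default = 1L),
        make_option("--duration", type = "double", default = 20),
        make_option("--out", type = "character", default = "protocol.json")))
      log_run(o)
      skill_fn <- function(s) {
        skill_state(coupling_strength = 12 * (1 - exp(-o$rate * (s - 1))))
      }
      res <- run_protocol(skill_fn,
                          osc = oscillator_params(duration = o$duration),
                          seed = o$seed)
      jsonlite::write_json(
        list(stop_reason = res$state$stop_reason,
             sessions = lapply(res$sessions, function(s) {
               list(bandwidth = s$bandwidth, scores = s$scores,
                    feedback = s$feedback, kr = s$kr)
             })),
        o$out, auto_unbox = TRUE, digits = NA, na = "null")
      message("stopped after ", res$state$session_count, " sessions (",
              res$state$stop_reason, "); wrote ", o$out)
      0L
    },
    "run-staircase" = {
      o <- opt(list(
        make_option("--observer-threshold", type = "double", default = 15,
                    dest = "threshold"),
        make_option("--lapse", type = "double", default = 0.02),
        make_option("--seed", type = "integer", default = 1L),
        make_option("--out", type = "character", default = "session.csv")))
      log_run(o)
      obs <- observer_model(o$threshold, lapse_rate = o$lapse)
      ses <- run_2afc_session(obs, seed = o$seed)
      utils::write.csv(ses$trials, o$out, row.names = FALSE)
      summ <- list(
        threshold = estimate_threshold(ses),
        reversals = lapply(ses$staircases, `[[`, "reversals"))
      jsonlite::write_json(summ, sub("\\.csv$", ".json", o$out),
                           auto_unbox = TRUE, digits = NA)
      message(sprintf("estimated threshold %.2f deg; wrote %s",
                      summ$threshold, o$out))
      0L
    },
    "analyze-transfer" = {
      o <- opt(list(
        make_option("--in", type = "character", dest = "input"),
        make_option("--pattern", type = "character", default = "ya_action"),
        make_option("--alpha", type = "double", default = 0.05),
        make_option("--out", type = "character", default = "transfer.json")))
      log_run(o)
      # input: CSV with participant, phase, then one column per session
      d <- utils::read.csv(o$input, check.names = FALSE)
      lam <- lambda_weights(o$pattern)
      phases <- unique(d$phase)
      res <- lapply(phases, function(ph) {
        x <- as.matrix(d[d$phase == ph, -(1:2)])
        ct <- contrast_test(x, lam)
        list(phase = ph, t = ct$t, df = ct$df, p = ct$p, g = ct$g)
      })
      ps <- vapply(res, `[[`, numeric(1), "p")
      names(ps) <- phases
      rej <- holm_bonferroni(ps, alpha = o$alpha)
      for (i in seq_along(res)) res[[i]]$reject <- unname(rej[i])
      jsonlite::write_json(res, o$out, auto_unbox = TRUE, digits = NA)
      message("wrote ", o$out)
      0L
    },
    "fit-learning" = {
      o <- opt(list(
        make_option("--in", type = "character", dest = "input"),
        make_option("--out", type = "character", default = "fit.json")))
      log_run(o)
      # input: CSV with columns session, mean_ptt
      d <- utils::read.csv(o$input)
      fit <- fit_learning_curve(d$mean_ptt, d$session)
      jsonlite::write_json(
        list(a = fit$a, b = fit$b, r_squared = fit$r_squared,
             learning_rate_S1 = fit$learning_rate_S1),
        o$out, auto_unbox = TRUE, digits = NA)
      message(sprintf("a = %.4f, b = %.4f, learning rate (S=1) = %.4f; wrote %s",
                      fit$a, fit$b, fit$learning_rate_S1, o$out))
      0L
    },
    stop("unknown subcommand: ", cmd, call. = FALSE)
  )
}, error = function(e) {
  message("error: ", conditionMessage(e))
  1L
})

quit(status = status)
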