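# Simulated experiments are deterministic per seed; cache them so the many
# tests that need full experiments do not re-simulate.
.exp_cache <- new.env(parent = emptyenv())

cached_experiment <- function(seed, modify = NULL) {
  key <- paste0("s", seed, "_",
                if (is.null(modify)) "default" else
                  paste(names(modify), unlist(lapply(modify, function(x)
                    paste(signif(unlist(x), 4), collapse = "_"))),
                    sep = "=", collapse = "|"))
  if (!is.null(.exp_cache[[key]])) return(.exp_cache[[key]])
  cfg <- default_config(seed = seed)
  if (!is.null(modify)) cfg <- utils::modifyList(cfg, modify)
  .exp_cache[[key]] <- simulate_experiment(cfg)
  .exp_cache[[key]]
}

# a minimal valid item-score vector
items_all <- function(v) stats::setNames(rep(v, 7L), mss_items())
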