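# Adaptive random-walk Metropolis bookkeeping (Roberts & Rosenthal style
# batch adaptation): per-component log proposal scales are nudged every
# `batch_size` iterations during warmup toward a target acceptance rate.

adapt_state <- function(n, init_scale = 0.1, target = 0.44) {
  list(log_scale = rep(log(init_scale), n), accepted = rep(0, n),
       attempted = rep(0, n), batch = 0L,
       target = rep_len(target, n))
}

adapt_record <- function(ad, i, accepted) {
  ad$attempted[i] <- ad$attempted[i] + 1
  ad$accepted[i] <- ad$accepted[i] + as.numeric(accepted)
  ad
}

adapt_maybe_update <- function(ad, iter, warmup, batch_size = 50L) {
  if (iter > warmup || iter %% batch_size != 0L) return(ad)
  ad$batch <- ad$batch + 1L
  delta <- min(0.1, 1 / sqrt(ad$batch))
  rate <- ifelse(ad$attempted > 0, ad$accepted / pmax(ad$attempted, 1),
                 ad$target)
  ad$log_scale <- ad$log_scale + ifelse(rate > ad$target, delta, -delta)
  ad$log_scale <- pmin(pmax(ad$log_scale, -12), 6)
  ad$accepted[] <- 0
  ad$attempted[] <- 0
  ad
}

# deterministic per-chain RNG seed derived from a user seed
chain_seed <- function(seed, chain) {
  (as.integer(seed) %% 1000000L) * 1009L + 97L * as.integer(chain)
}
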