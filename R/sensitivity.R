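# parameter registry for the one-at-a-time sensitivity analysis:
# each entry scales the parameter by a factor (the perturbation), clamping
# where the parameter has a bounded domain
.sens_ft_params <- c("growth_rate", "competition_strength",
                     "nest_suitability", "res_suitability",
                     "emigration_mu", "emigration_omega",
                     "dispersal_mean", "dispersal_sd", "disturbance_effect")
.sens_global_params <- c("disturbance_prob", "weather_std", "dispersal_tries",
                         "trans_effect_res", "trans_effect_nest",
                         "trans_effect_nest_res")

scale_param <- function(config, community, param, transform) {
  nest_cols <- paste0("nest_", lu_names())
  forage_cols <- paste0("forage_", lu_names())
  switch(param,
    growth_rate = community$r <- transform(community$r),
    competition_strength = community$c <- transform(community$c),
    nest_suitability =
      community[nest_cols] <- lapply(community[nest_cols], transform),
    res_suitability =
      community[forage_cols] <- lapply(community[forage_cols], transform),
    emigration_mu =
      community$emigration_mu <- pmin(1, transform(community$emigration_mu)),
    emigration_omega =
      community$emigration_omega <- transform(community$emigration_omega),
    dispersal_mean = community$disp_mean <- transform(community$disp_mean),
    dispersal_sd = community$disp_sd <- transform(community$disp_sd),
    disturbance_effect =
      community$dist_eff <- pmin(1, pmax(0, transform(community$dist_eff))),
    disturbance_prob = {
      p <- pmin(1, pmax(0, transform(config$disturbance_prob)))
      p["water"] <- 0
      config$disturbance_prob <- p
    },
    weather_std = config$weather_std <- max(0, transform(config$weather_std)),
    dispersal_tries = config$dispersal_tries <-
      max(1L, as.integer(round(transform(config$dispersal_tries)))),
    trans_effect_res =
      community$trans_effect_res <- transform(community$trans_effect_res),
    trans_effect_nest =
      community$trans_effect_nest <- transform(community$trans_effect_nest),
    trans_effect_nest_res = {
      community$trans_effect_res <- transform(community$trans_effect_res)
      community$trans_effect_nest <- transform(community$trans_effect_nest)
    },
    stop("unknown sensitivity parameter: ", param))
  list(config = config, community = community)
}

#' Build a one-at-a-time sensitivity plan
#'
#' Every numerical parameter gets four scaled variants (-25%, -10%, +10%,
#' +25%). Functional-type-specific parameters additionally get two spread
#' variants that shrink or stretch the differences between types by 50%
#' relative to the lowest value: `v' = v_min + (v - v_min) * (1 +/- 0.5)`
#' (per land-use column for the suitability tables). The two non-numerical
#' parameters get reversal variants: ABZ conversion walking arable patches
#' in ascending instead of descending area order, and the competition factor
#' reversed (`c -> 5 - c`, so the strongest competitor becomes the weakest).
#' Exactly one parameter differs from the baseline per variant.
#'
#' @param config Baseline [sim_config()].
#' @param community Baseline `bee_community`.
#' @return A `sensitivity_plan`: baseline plus a list of variants, each with
#'   `parameter`, `perturbation` label, and the modified config/community.
#' @export
build_plan <- function(config, community) {
  variants <- list()
  add <- function(parameter, perturbation, config2, community2) {
    variants[[length(variants) + 1]] <<- list(
      parameter = parameter, perturbation = perturbation,
      config = config2, community = community2)
  }
  for (param in c(.sens_ft_params, .sens_global_params)) {
    for (pct in c(-25, -10, 10, 25)) {
      mod <- scale_param(config, community, param,
                         function(v) v * (1 + pct / 100))
      add(param, sprintf("%+d%%", pct), mod$config, mod$community)
    }
    if (param %in% .sens_ft_params) {
      for (sp in c(-50, 50)) {
        fac <- 1 + sp / 100
        spread <- function(v) min(v) + (v - min(v)) * fac
        mod <- scale_param(config, community, param, spread)
        add(param, sprintf("spread%+d%%", sp), mod$config, mod$community)
      }
    }
  }
  ord_cfg <- config
  ord_cfg$abz_order <- "ascending"
  add("order", "reversed", ord_cfg, community)
  rev_com <- community
  rev_com$c <- 5 - rev_com$c
  add("competition_strength", "reversed", config, rev_com)
  structure(list(baseline = list(config = config, community = community),
                 variants = variants),
            class = "sensitivity_plan")
}

#' @export
print.sensitivity_plan <- function(x, ...) {
  cat("<sensitivity_plan> ", length(x$variants), " variants over ",
      length(unique(vapply(x$variants, `[[`, "", "parameter"))),
      " parameters\n", sep = "")
  invisible(x)
}

run_endpoints <- function(ls, community, config, fractions) {
  scen <- run_scenarios(ls, community, config, fractions)
  do.call(rbind, lapply(seq_along(fractions), function(fi) {
    run <- scen$runs[[1]][[fi]]
    final <- run$totals[, dim(run$totals)[2], , drop = TRUE]
    if (is.null(dim(final))) final <- matrix(final, nrow = 1)
    data.frame(fraction = fractions[fi],
               ft_richness = mean(apply(final, 1, ft_richness)),
               shannon = mean(apply(final, 1, function(x)
                 if (sum(x) > 0) shannon(x) else 0)))
  }))
}

#' Run a sensitivity plan
#'
#' Simulates the baseline and every variant on one landscape across the ABZ
#' fractions and reports, per variant, fraction and endpoint (mean
#' functional richness and mean Shannon diversity at the final year over
#' repetitions), the relative change against the baseline mean:
#' `(variant - baseline) / baseline`.
#'
#' @param plan A `sensitivity_plan`.
#' @param ls A `bee_landscape`.
#' @param fractions ABZ fractions to simulate (default the standard
#'   gradient).
#' @return Tidy data frame: `parameter`, `perturbation`, `fraction`,
#'   `endpoint`, `value`, `baseline`, `relative_change`. Baseline rows are
#'   included with `parameter = "baseline"`.
#' @export
run_plan <- function(plan, ls,
                     fractions = c(0, 0.05, 0.1, 0.15, 0.2, 0.25,
                                   0.5, 0.75, 1)) {
  base <- run_endpoints(ls, plan$baseline$community, plan$baseline$config,
                        fractions)
  long <- function(df, parameter, perturbation) {
    data.frame(parameter = parameter, perturbation = perturbation,
               fraction = rep(df$fraction, 2),
               endpoint = rep(c("ft_richness", "shannon"),
                              each = nrow(df)),
               value = c(df$ft_richness, df$shannon))
  }
  out <- long(base, "baseline", "0%")
  for (v in plan$variants) {
    df <- run_endpoints(ls, v$community, v$config, fractions)
    out <- rbind(out, long(df, v$parameter, v$perturbation))
  }
  base_long <- long(base, "baseline", "0%")
  key <- paste(out$fraction, out$endpoint)
  bkey <- paste(base_long$fraction, base_long$endpoint)
  out$baseline <- base_long$value[match(key, bkey)]
  out$relative_change <- ifelse(out$baseline != 0,
                                (out$value - out$baseline) / out$baseline,
                                NA_real_)
  out
}
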