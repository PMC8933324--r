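#' Trait levels of the functional-type space
#'
#' Five traits define a functional bee type: foraging distance (short,
#' medium, long), diet breadth (oligolectic, polylectic), flying period
#' (first or second half of the year, or both), nesting preference (hypogean,
#' endogeic) and parasite-host status (yes, no) -- 72 possible profiles.
#'
#' @return Named list of the admissible levels per trait.
#' @export
trait_levels <- function() {
  list(foraging_distance = c("short", "medium", "long"),
       diet = c("oligolectic", "polylectic"),
       flying_period = c("first", "second", "both"),
       nesting = c("hypogean", "endogeic"),
       parasite_host = c("yes", "no"))
}

check_profile <- function(profile) {
  lv <- trait_levels()
  for (tr in names(lv)) {
    v <- profile[[tr]]
    if (is.null(v) || length(v) != 1 || !v %in% lv[[tr]])
      stop("invalid trait level for ", tr, ": ",
           if (is.null(v)) "missing" else v)
  }
  invisible(profile)
}

# trait-to-parameter lookup tables (land-use order: bare, arable, forest,
# grassland, urban, water)
.r_table <- c(long.yes = 2.5, long.no = 3, medium.yes = 3.5, medium.no = 4,
              short.yes = 4.5, short.no = 5)
.c_table <- c(long.polylectic = 0, long.oligolectic = 1,
              medium.polylectic = 2, medium.oligolectic = 3,
              short.polylectic = 4, short.oligolectic = 5)
.forage_table <- rbind(
  oligolectic.one  = c(0, 0.40, 0.4, 1.0, 0.4, 0),
  oligolectic.both = c(0, 0.60, 0.6, 1.5, 0.6, 0),
  polylectic.one   = c(0, 0.70, 0.6, 1.0, 0.6, 0),
  polylectic.both  = c(0, 1.05, 0.9, 1.5, 0.9, 0))
.nest_table <- rbind(
  hypogean = c(0, 0.1, 1.0, 0.3, 0.7, 0),
  endogeic = c(1, 0.3, 0.1, 0.7, 0.1, 0))
.disp_table <- rbind(long = c(600, 60), medium = c(300, 30), short = c(100, 10))
.dist_eff_table <- c(hypogean = 0.3, endogeic = 0.9)

#' Derive model parameters from a trait profile
#'
#' Pure lookup in the trait-to-parameter table: growth rate `r` by (foraging
#' distance, parasite-host status); competition factor `c` by (foraging
#' distance, diet); foraging suitability per land-use class by (diet, flying
#' period); nesting suitability and disturbance effect by nesting preference;
#' dispersal kernel mean/sd by foraging distance (600/60, 300/30, 100/10 m).
#' The ABZ transformation effects default to 1.0 (type-unspecific), the
#' density-compensation exponent `b` to 1, and the emigration parameters to
#' `mu = 0.2`, `omega = 2`; all are overridable (used by the sensitivity
#' harness).
#'
#' @param profile Named list/vector with entries `foraging_distance`, `diet`,
#'   `flying_period`, `nesting`, `parasite_host` (see [trait_levels()]).
#' @param overrides Named list of parameter overrides applied after the
#'   lookup (e.g. `list(b = 1.2, emigration_mu = 0.25)`).
#' @param swap_nesting_rows Swap the two nesting-suitability value rows
#'   between the hypogean and endogeic labels (exploration flag; the printed
#'   table rows are the default).
#' @return Named list of parameters: `r`, `c`, `forage_suitability` and
#'   `nest_suitability` (named over land-use classes), `disp_mean`,
#'   `disp_sd`, `dist_eff`, `trans_effect_nest`, `trans_effect_res`, `b`,
#'   `emigration_mu`, `emigration_omega`.
#' @examples
#' derive_parameters(list(foraging_distance = "short", diet = "oligolectic",
#'                        flying_period = "first", nesting = "endogeic",
#'                        parasite_host = "no"))
#' @export
derive_parameters <- function(profile, overrides = list(),
                              swap_nesting_rows = FALSE) {
  check_profile(profile)
  fp <- if (profile$flying_period == "both") "both" else "one"
  nest_row <- profile$nesting
  if (swap_nesting_rows)
    nest_row <- setdiff(c("hypogean", "endogeic"), nest_row)
  disp <- .disp_table[profile$foraging_distance, ]
  pars <- list(
    r = unname(.r_table[paste(profile$foraging_distance,
                              profile$parasite_host, sep = ".")]),
    c = unname(.c_table[paste(profile$foraging_distance,
                              profile$diet, sep = ".")]),
    forage_suitability = setNames(
      .forage_table[paste(profile$diet, fp, sep = "."), ], lu_names()),
    nest_suitability = setNames(.nest_table[nest_row, ], lu_names()),
    disp_mean = disp[1], disp_sd = disp[2],
    dist_eff = unname(.dist_eff_table[profile$nesting]),
    trans_effect_nest = 1.0, trans_effect_res = 1.0,
    b = 1.0, emigration_mu = 0.2, emigration_omega = 2.0)
  for (nm in names(overrides)) pars[[nm]] <- overrides[[nm]]
  pars
}

all_profiles <- function() {
  g <- expand.grid(trait_levels(), stringsAsFactors = FALSE,
                   KEEP.OUT.ATTRS = FALSE)
  g[do.call(order, g), , drop = FALSE]
}

build_community <- function(profiles, overrides = list(),
                            swap_nesting_rows = FALSE, n_species = NULL) {
  S <- nrow(profiles)
  if (S == 0) {
    # typed empty community (one row built from a dummy profile, dropped)
    tmpl <- build_community(all_profiles()[1, , drop = FALSE])
    return(tmpl[0, , drop = FALSE])
  }
  rows <- lapply(seq_len(S), function(k) {
    p <- as.list(profiles[k, ])
    pars <- derive_parameters(p, overrides, swap_nesting_rows)
    data.frame(
      p, r = pars$r, c = pars$c,
      disp_mean = pars$disp_mean, disp_sd = pars$disp_sd,
      dist_eff = pars$dist_eff,
      trans_effect_nest = pars$trans_effect_nest,
      trans_effect_res = pars$trans_effect_res,
      b = pars$b, emigration_mu = pars$emigration_mu,
      emigration_omega = pars$emigration_omega,
      as.list(setNames(pars$forage_suitability,
                       paste0("forage_", lu_names()))),
      as.list(setNames(pars$nest_suitability,
                       paste0("nest_", lu_names()))),
      stringsAsFactors = FALSE)
  })
  com <- do.call(rbind, rows)
  com <- cbind(ft_id = sprintf("FT%02d", seq_len(S)), com,
               stringsAsFactors = FALSE)
  com$n_species <- if (is.null(n_species)) 1L else n_species
  rownames(com) <- NULL
  class(com) <- c("bee_community", "data.frame")
  com
}

#' Classify a species trait table into functional types
#'
#' Collapses species rows sharing identical trait profiles into one
#' functional type per distinct profile; the species count per type is kept
#' as metadata (`n_species`). Parameters are derived per profile via
#' [derive_parameters()].
#'
#' @param rows Data frame with columns `species`, `foraging_distance`,
#'   `diet`, `flying_period`, `nesting`, `parasite_host` (a CSV read with
#'   [utils::read.csv()] works as-is).
#' @param overrides,swap_nesting_rows Passed to [derive_parameters()].
#' @return A `bee_community` data frame (one row per functional type).
#' @export
classify_trait_table <- function(rows, overrides = list(),
                                 swap_nesting_rows = FALSE) {
  traits <- names(trait_levels())
  miss <- setdiff(traits, names(rows))
  if (length(miss) > 0)
    stop("malformed trait table: missing column(s) ",
         paste(miss, collapse = ", "))
  if (nrow(rows) == 0) {
    warning("empty trait table: returning an empty community")
    return(build_community(all_profiles()[0, , drop = FALSE]))
  }
  for (k in seq_len(nrow(rows))) check_profile(as.list(rows[k, traits]))
  key <- do.call(paste, c(rows[traits], sep = "|"))
  first <- !duplicated(key)
  profiles <- rows[first, traits, drop = FALSE]
  ord <- do.call(order, profiles)
  profiles <- profiles[ord, , drop = FALSE]
  counts <- as.integer(table(key)[do.call(paste, c(profiles, sep = "|"))])
  rownames(profiles) <- NULL
  build_community(profiles, overrides, swap_nesting_rows, n_species = counts)
}

#' Default functional-type roster
#'
#' A deterministic, seeded sample of `n` distinct trait profiles from the
#' 72-profile space, stratified so that every level of every trait is
#' represented whenever `n >= 6`. The default of 28 types matches the size
#' of a field community of 56 solitary bee species collapsed to functional
#' types.
#'
#' @param n Number of functional types (1-72, default 28).
#' @param seed Integer seed (default 20). Same `n` and `seed` give the same
#'   roster.
#' @param overrides,swap_nesting_rows Passed to [derive_parameters()].
#' @return A `bee_community` data frame.
#' @export
default_community <- function(n = 28, seed = 20, overrides = list(),
                              swap_nesting_rows = FALSE) {
  if (n < 1 || n > 72) stop("n must lie in 1..72")
  prof <- all_profiles()
  with_local_seed(seed, {
    perm <- sample.int(nrow(prof))
    chosen <- integer(0)
    if (n >= 6) {
      # greedy set-cover pass: repeatedly take the earliest profile in the
      # permutation adding the most uncovered trait levels (at most 4 picks,
      # since one profile covers one level of each of the five traits)
      lv <- trait_levels()
      covered <- lapply(lv, function(x) setNames(rep(FALSE, length(x)), x))
      n_adds <- function(k) sum(vapply(names(lv), function(tr)
        !covered[[tr]][[prof[k, tr]]], logical(1)))
      while (!all(unlist(covered))) {
        gains <- vapply(setdiff(perm, chosen), n_adds, numeric(1))
        pick <- setdiff(perm, chosen)[which.max(gains)]
        chosen <- c(chosen, pick)
        for (tr in names(lv)) covered[[tr]][[prof[pick, tr]]] <- TRUE
      }
    }
    fill <- setdiff(perm, chosen)
    chosen <- c(chosen, fill[seq_len(n - length(chosen))])
    chosen <- sort(chosen[seq_len(n)])
    build_community(prof[chosen, , drop = FALSE], overrides,
                    swap_nesting_rows)
  })
}

#' Do two flying periods overlap?
#'
#' Types compete only when their activity windows intersect: `"first"` and
#' `"second"` are disjoint; `"both"` overlaps everything (bivoltine types
#' compete with early and late fliers alike). Symmetric and reflexive.
#'
#' @param p1,p2 Flying-period values (`"first"`, `"second"`, `"both"`).
#' @return Logical.
#' @export
flying_periods_overlap <- function(p1, p2) {
  lv <- trait_levels()$flying_period
  if (!p1 %in% lv || !p2 %in% lv) stop("invalid flying period")
  p1 == "both" || p2 == "both" || p1 == p2
}

# integer period codes used by the simulation core: first=0, second=1, both=2
period_code <- function(period) {
  match(period, trait_levels()$flying_period) - 1L
}

#' @export
print.bee_community <- function(x, ...) {
  cat("<bee_community> ", nrow(x), " functional types\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("... ", nrow(x) - 10, " more rows\n", sep = "")
  invisible(x)
}
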