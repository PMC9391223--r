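#' Helmert/sum contrast scheme
#'
#' The numeric codes used for the three design factors. Stimulus type is a
#' centred two-level contrast (backward -1/2, forward +1/2). Group is a
#' three-level Helmert pair: contrast 1 compares the passive control group
#' (-2/3) with the mean of the active control and experimental groups
#' (+1/3 each); contrast 2 compares active control (-1/2) with
#' experimental (+1/2), passive coded 0. Test phase is the analogous pair:
#' contrast 1 compares baseline T0 (-2/3) with the mean of T1 and T2
#' (+1/3); contrast 2 compares T1 (-1/2) with T2 (+1/2), T0 coded 0. All
#' columns are additionally centred on their observed means before
#' products are formed.
#'
#' @export
contrast_scheme <- function() {
  list(
    stimulus = c(backward = -1/2, forward = 1/2),
    group_c1 = c(passive = -2/3, active = 1/3, experimental = 1/3),
    group_c2 = c(passive = 0, active = -1/2, experimental = 1/2),
    phase_c1 = c(T0 = -2/3, T1 = 1/3, T2 = 1/3),
    phase_c2 = c(T0 = 0, T1 = -1/2, T2 = 1/2)
  )
}

# fixed-effect slope columns in model order: 5 mains, 8 two-way products,
# 4 three-way products (no products within a factor)
lmm_fixed_terms <- function() {
  c("stim_c", "grp1_c", "grp2_c", "phs1_c", "phs2_c",
    "stim_grp1", "stim_grp2", "stim_phs1", "stim_phs2",
    "grp1_phs1", "grp1_phs2", "grp2_phs1", "grp2_phs2",
    "stim_grp1_phs1", "stim_grp1_phs2", "stim_grp2_phs1", "stim_grp2_phs2")
}

#' Append centred contrast columns and their products
#'
#' Adds the five centred contrast columns and the twelve between-factor
#' interaction products (products of the centred columns; no within-factor
#' products) to a trial feature table or connectivity pair table.
#'
#' @param table data.frame with `stimulus_type` (optional), `group`, `phase`
#' @param scheme codes from [contrast_scheme()]
#' @return the table with numeric design columns appended
#' @export
code_contrasts <- function(table, scheme = contrast_scheme()) {
  ctr <- function(x) x - mean(x)
  lookup <- function(codes, labels, what) {
    if (!all(labels %in% names(codes))) {
      stop("unknown ", what, " label(s): ",
           paste(setdiff(unique(labels), names(codes)), collapse = ", "))
    }
    unname(codes[labels])
  }
  has_stim <- "stimulus_type" %in% names(table)
  if (has_stim) {
    table$stim_c <- ctr(lookup(scheme$stimulus, table$stimulus_type,
                               "stimulus"))
  }
  table$grp1_c <- ctr(lookup(scheme$group_c1, table$group, "group"))
  table$grp2_c <- ctr(lookup(scheme$group_c2, table$group, "group"))
  table$phs1_c <- ctr(lookup(scheme$phase_c1, table$phase, "phase"))
  table$phs2_c <- ctr(lookup(scheme$phase_c2, table$phase, "phase"))
  for (g in c("grp1", "grp2")) {
    for (p in c("phs1", "phs2")) {
      table[[paste(g, p, sep = "_")]] <-
        table[[paste0(g, "_c")]] * table[[paste0(p, "_c")]]
    }
  }
  if (has_stim) {
    for (f in c("grp1", "grp2", "phs1", "phs2")) {
      table[[paste0("stim_", f)]] <- table$stim_c * table[[paste0(f, "_c")]]
    }
    for (g in c("grp1", "grp2")) {
      for (p in c("phs1", "phs2")) {
        table[[paste("stim", g, p, sep = "_")]] <-
          table$stim_c * table[[paste(g, p, sep = "_")]]
      }
    }
  }
  table
}
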