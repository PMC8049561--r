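#' Demography scenarios
#'
#' A `demography_scenario` describes a population history as tables of
#' populations (with diploid effective sizes), clean splits, lineage merges,
#' admixture pulses that found a population, one-off migration pulses and
#' continuous migration epochs. All times are in generations before present.
#' Scenarios are consumed by [simulate_genotypes()] and serialize losslessly
#' to JSON via [write_scenario()] / [read_scenario()].
#'
#' @param name Scenario name.
#' @param populations Tibble with columns `name` (identifier), `size`
#'   (diploid Ne), `samples` (diploid individuals to sample; 0 or `NA` for
#'   unsampled ghost lineages) and `label` (output population label).
#' @param splits Tibble with `time`, `derived` (list-column of character
#'   vectors) and `ancestral`.
#' @param merges Tibble with `time`, `derived`, `into` (an existing branch).
#' @param admixtures Tibble with `time`, `derived`, `ancestral1`,
#'   `ancestral2`, `proportion` (ancestral1's share).
#' @param pulses Tibble with `time`, `donor`, `recipient`, `proportion`
#'   (forward-time one-generation gene flow).
#' @param migrations Tibble with `donor`, `recipient`, `rate`, `start`, `end`
#'   (forward-time continuous migration, `rate` = fraction of the recipient
#'   replaced per generation).
#' @return An object of class `demography_scenario`.
#' @export
demography_scenario <- function(name, populations, splits = NULL, merges = NULL,
                                admixtures = NULL, pulses = NULL,
                                migrations = NULL) {
  empty <- function(x, proto) if (is.null(x) || nrow(x) == 0) proto else tibble::as_tibble(x)
  sc <- structure(list(
    name = name,
    populations = tibble::as_tibble(populations),
    splits = empty(splits, tibble::tibble(time = double(), derived = list(),
                                          ancestral = character())),
    merges = empty(merges, tibble::tibble(time = double(), derived = character(),
                                          into = character())),
    admixtures = empty(admixtures, tibble::tibble(time = double(), derived = character(),
                                                  ancestral1 = character(),
                                                  ancestral2 = character(),
                                                  proportion = double())),
    pulses = empty(pulses, tibble::tibble(time = double(), donor = character(),
                                          recipient = character(),
                                          proportion = double())),
    migrations = empty(migrations, tibble::tibble(donor = character(),
                                                  recipient = character(),
                                                  rate = double(), start = double(),
                                                  end = double()))
  ), class = "demography_scenario")
  validate_scenario(sc)
}

validate_scenario <- function(sc) {
  pops <- sc$populations
  stopifnot(all(c("name", "size") %in% names(pops)))
  if (!"samples" %in% names(pops)) sc$populations$samples <- NA_integer_
  if (!"label" %in% names(pops)) sc$populations$label <- pops$name
  all_named <- c(unlist(sc$splits$derived), sc$splits$ancestral,
                 sc$merges$derived, sc$merges$into,
                 sc$admixtures$derived, sc$admixtures$ancestral1,
                 sc$admixtures$ancestral2,
                 sc$pulses$donor, sc$pulses$recipient,
                 sc$migrations$donor, sc$migrations$recipient)
  unknown <- setdiff(all_named, sc$populations$name)
  if (length(unknown)) {
    stop("events reference undeclared populations: ",
         paste(unique(unknown), collapse = ", "), call. = FALSE)
  }
  if (any(sc$admixtures$proportion < 0 | sc$admixtures$proportion > 1)) {
    stop("admixture proportions must lie in [0, 1]", call. = FALSE)
  }
  if (any(sc$pulses$proportion < 0 | sc$pulses$proportion > 1)) {
    stop("pulse proportions must lie in [0, 1]", call. = FALSE)
  }
  sc
}

#' @export
print.demography_scenario <- function(x, ...) {
  cat("<demography_scenario> ", x$name, ": ",
      sum(!is.na(x$populations$samples) & x$populations$samples > 0),
      " sampled populations (", nrow(x$populations), " branches), ",
      nrow(x$admixtures), " admixture event(s), ",
      nrow(x$migrations), " migration epoch(s)\n", sep = "")
  invisible(x)
}

#' Serialize a scenario to human-readable JSON
#'
#' @param sc A [demography_scenario()].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_scenario <- function(sc, path) {
  adm <- sc$admixtures
  body <- list(
    name = sc$name,
    populations = sc$populations,
    splits = if (nrow(sc$splits)) sc$splits else NULL,
    merges = if (nrow(sc$merges)) sc$merges else NULL,
    admixtures = if (nrow(adm)) {
      tibble::tibble(time = adm$time, derived = adm$derived,
                     ancestral = purrr::map2(adm$ancestral1, adm$ancestral2, c),
                     proportion = adm$proportion)
    } else NULL,
    pulses = if (nrow(sc$pulses)) sc$pulses else NULL,
    migrations = if (nrow(sc$migrations)) sc$migrations else NULL
  )
  jsonlite::write_json(body[!vapply(body, is.null, logical(1))], path,
                       dataframe = "rows", auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a scenario written by [write_scenario()]
#'
#' @param path JSON file.
#' @return A [demography_scenario()].
#' @export
read_scenario <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = TRUE)
  splits <- NULL
  if (!is.null(js$splits)) {
    splits <- tibble::as_tibble(js$splits)
    splits$derived <- lapply(splits$derived, as.character)
  }
  admixtures <- NULL
  if (!is.null(js$admixtures)) {
    a <- tibble::as_tibble(js$admixtures)
    admixtures <- tibble::tibble(
      time = a$time, derived = a$derived,
      ancestral1 = vapply(a$ancestral, `[`, character(1), 1),
      ancestral2 = vapply(a$ancestral, `[`, character(1), 2),
      proportion = a$proportion)
  }
  demography_scenario(js$name, tibble::as_tibble(js$populations),
                      splits = splits,
                      merges = if (is.null(js$merges)) NULL else tibble::as_tibble(js$merges),
                      admixtures = admixtures,
                      pulses = if (is.null(js$pulses)) NULL else tibble::as_tibble(js$pulses),
                      migrations = if (is.null(js$migrations)) NULL else tibble::as_tibble(js$migrations))
}

# Branch parameters of the 16-population benchmark tree. Split times and
# per-branch sizes are calibrated so that (i) population 9 leaves the donor
# lineage of the recent pulse at generation 280 and the pulse donor splits
# from the 5/6 lineage at generation 250, (ii) mean pairwise FST among
# populations 1-5 sits in the <0.001-0.005 window, (iii) reference 0 is
# differentially related to candidate sources 1-5 with bias ordered 1 > 2 >
# 3 > 4, and (iv) rotating references 5/9 carry enough post-split drift to
# reject substitute sources at desk-scale SNP counts. See the methods
# vignette for the calibration procedure.
standard_tree_params <- function() {
  list(
    t_pulse14 = 100, alpha_default = 0.5,
    t_pulse15 = 400, beta = 0.55,
    t_56 = 150, t_14a = 250, t_clade_root = 1300,
    t_ladder = c(150, 490, 830, 1170),   # (0,1), +2, +3, +4
    t_9 = 280, t_8 = 1100, t_710 = 500, t_7 = 2400, t_11 = 3300,
    t_13 = 2500, t_15a = 700, t_15b_join12 = 1500, t_12 = 1800,
    t_left_right = 3700,
    ne_terminal = 1e5, ne_ladder = 2.5e4, ne_sep = 2.5e4,
    ne_m56a = 2.5e4, ne_r1 = 2.5e4, ne_deep = 2.5e4, ne_lc = 2.5e4,
    ne_lc2 = 1e5, ne_spine = 1e5, ne_15b = 2e5, ne_ref_mid = 2e5,
    ne_ref_deep = 4e5
  )
}

#' Build the 16-population benchmark tree
#'
#' Sixteen sampled populations with two admixture events: a recent two-way
#' pulse forming population 14 (proportion `alpha` from a donor lineage
#' related to populations 5/6, the rest from a donor that population 9 split
#' away from at generation 280) and an older pulse forming population 15
#' (proportion 0.55, fixed). Populations 0-6 form a closely related clade in
#' which reference population 0 is differentially related to candidate
#' sources 1-5; populations 8 and 9 are symmetrically related to all
#' references of the standard model. The standard qpAdm model on this history
#' is target 14, sources 5 and 9, references 0, 7, 10, 12, 13.
#'
#' @param alpha Admixture proportion of the 5/6-related donor into
#'   population 14, in `[0, 1]`.
#' @return A [demography_scenario()].
#' @export
build_standard_tree <- function(alpha = 0.5) {
  stopifnot(alpha >= 0, alpha <= 1)
  pr <- standard_tree_params()
  pops <- tibble::tribble(
    ~name, ~size, ~samples, ~label,
    "p0", pr$ne_terminal, 10L, "0",
    "p1", pr$ne_terminal, 10L, "1",
    "p2", pr$ne_terminal, 10L, "2",
    "p3", pr$ne_terminal, 10L, "3",
    "p4", pr$ne_terminal, 10L, "4",
    "p5", pr$ne_terminal, 10L, "5",
    "p6", pr$ne_terminal, 10L, "6",
    "p7", pr$ne_terminal, 10L, "7",
    "p8", pr$ne_ref_mid, 10L, "8",
    "p9", pr$ne_terminal, 10L, "9",
    "p10", pr$ne_terminal, 10L, "10",
    "p11", pr$ne_ref_mid, 10L, "11",
    "p12", pr$ne_ref_mid, 10L, "12",
    "p13", pr$ne_ref_deep, 10L, "13",
    "p14", pr$ne_terminal, 10L, "14",
    "p15", pr$ne_terminal, 10L, "15",
    "K1", pr$ne_ladder, 0L, "K1",
    "K2", pr$ne_ladder, 0L, "K2",
    "K3", pr$ne_ladder, 0L, "K3",
    "K4", pr$ne_sep, 0L, "K4",
    "N56", pr$ne_terminal, 0L, "N56",
    "M56a", pr$ne_m56a, 0L, "M56a",
    "L14a", pr$ne_terminal, 0L, "L14a",
    "L14b", pr$ne_terminal, 0L, "L14b",
    "LC", pr$ne_lc, 0L, "LC",
    "LC2", pr$ne_lc2, 0L, "LC2",
    "R1", pr$ne_r1, 0L, "R1",
    "R2", pr$ne_lc2, 0L, "R2",
    "R3", pr$ne_deep, 0L, "R3",
    "L7", pr$ne_deep, 0L, "L7",
    "L11a", pr$ne_ref_mid, 0L, "L11a",
    "L11b", pr$ne_deep, 0L, "L11b",
    "P15a", pr$ne_terminal, 0L, "P15a",
    "P15b", pr$ne_15b, 0L, "P15b",
    "L12", pr$ne_ref_mid, 0L, "L12",
    "RC", pr$ne_deep, 0L, "RC",
    "ANC", pr$ne_deep, 0L, "ANC"
  )
  splits <- tibble::tibble(
    time = c(pr$t_ladder, pr$t_clade_root, pr$t_56, pr$t_14a,
             pr$t_9, pr$t_8, pr$t_710, pr$t_7, pr$t_15a,
             pr$t_13, pr$t_11,
             pr$t_15b_join12, pr$t_12,
             pr$t_left_right),
    derived = list(
      c("p0", "p1"), c("K1", "p2"), c("K2", "p3"), c("K3", "p4"),
      c("K4", "M56a"),
      c("p5", "p6"), c("N56", "L14a"),
      c("p9", "L14b"), c("R1", "p8"), c("p7", "p10"), c("R2", "L7"),
      c("p11", "P15a"),
      c("L11a", "p13"), c("R3", "L11b"),
      c("p12", "P15b"), c("LC", "L12"),
      c("LC2", "RC")),
    ancestral = c("K1", "K2", "K3", "K4", "LC",
                  "N56", "M56a",
                  "R1", "R2", "L7", "R3",
                  "L11a",
                  "L11b", "RC",
                  "L12", "LC2",
                  "ANC")
  )
  admixtures <- tibble::tibble(
    time = c(pr$t_pulse14, pr$t_pulse15),
    derived = c("p14", "p15"),
    ancestral1 = c("L14a", "P15a"),
    ancestral2 = c("L14b", "P15b"),
    proportion = c(alpha, pr$beta)
  )
  demography_scenario(sprintf("standard_tree_alpha%.3g", alpha), pops,
                      splits = splits, admixtures = admixtures)
}

#' Standard tree plus gene flow involving a reference population
#'
#' Adds a one-generation pulse of proportion `gamma` to the standard tree,
#' by default from reference population 10 into source population 9, at
#' generation 200 (after population 9 split from the pulse-donor lineage at
#' generation 280 — an assumption violation that biases the admixture
#' estimate) or 350 (before the split — harmless).
#'
#' @inheritParams build_standard_tree
#' @param gamma Pulse proportion.
#' @param pulse_generation Pulse time; with the default donor/recipient pair,
#'   200 postdates and 350 predates the generation-280 split.
#' @param donor,recipient Population labels (`"0"`-`"15"`) for the forward-time
#'   flow.
#' @return A [demography_scenario()].
#' @export
build_reference_geneflow_tree <- function(alpha = 0.5, gamma = 0.05,
                                          pulse_generation = 200,
                                          donor = "10", recipient = "9") {
  stopifnot(gamma >= 0, gamma <= 1)
  sc <- build_standard_tree(alpha)
  branch_of <- function(label, time) {
    name <- sc$populations$name[match(label, sc$populations$label)]
    if (is.na(name)) stop("unknown population label: ", label, call. = FALSE)
    repeat {
      span <- branch_interval(sc, name)
      if (time < span[2]) return(name)
      name <- branch_parent(sc, name)
      if (is.na(name)) stop("no branch ancestral to ", label, " at time ", time,
                            call. = FALSE)
    }
  }
  if (gamma > 0) {
    sc$pulses <- tibble::tibble(
      time = pulse_generation,
      donor = branch_of(donor, pulse_generation),
      recipient = branch_of(recipient, pulse_generation),
      proportion = gamma)
  }
  sc$name <- sprintf("reference_geneflow_a%.3g_g%.3g_t%d", alpha, gamma,
                     as.integer(pulse_generation))
  sc
}

# Existence interval of a branch: birth is the time it appears as the
# ancestor of a split (0 for present-day branches), death the time it merges
# into its parent (Inf for the root).
branch_interval <- function(sc, name) {
  birth <- 0
  a <- which(sc$splits$ancestral == name)
  if (length(a)) birth <- max(sc$splits$time[a])
  i <- which(vapply(sc$splits$derived, function(d) name %in% d, logical(1)))
  if (length(i)) return(c(birth, sc$splits$time[i]))
  j <- which(sc$merges$derived == name)
  if (length(j)) return(c(birth, sc$merges$time[j]))
  k <- which(sc$admixtures$derived == name)
  if (length(k)) return(c(birth, sc$admixtures$time[k]))
  c(birth, Inf)
}

branch_parent <- function(sc, name) {
  i <- which(vapply(sc$splits$derived, function(d) name %in% d, logical(1)))
  if (length(i)) return(sc$splits$ancestral[i])
  j <- which(sc$merges$derived == name)
  if (length(j)) return(sc$merges$into[j])
  NA_character_
}

#' Standard tree expanded to 118 populations
#'
#' At 51 positions spread over the branches of the standard tree, a new
#' lineage branches off and then itself splits into two sampled populations
#' 50 generations later, giving 16 + 2 x 51 = 118 populations. New
#' populations inherit the effective size of the branch they split from.
#' Used to study the effect of very large reference sets.
#'
#' @inheritParams build_standard_tree
#' @return A [demography_scenario()].
#' @export
build_many_pops_tree <- function(alpha = 0.5) {
  sc <- build_standard_tree(alpha)
  host <- setdiff(sc$populations$name, c("p14", "p15", "ANC"))
  spans <- lapply(host, function(nm) branch_interval(sc, nm))
  # a star at fraction f of the branch needs the merge to happen while the
  # host exists and the new pair's own split (50 generations earlier) to
  # postdate the present
  star_time <- function(s, f) {
    t <- s[1] + f * (s[2] - s[1])
    t <- max(t, 65, s[1] + 5)
    if (t > s[2] - 5) NA_real_ else t
  }
  ok <- vapply(spans, function(s) is.finite(s[2]) && !is.na(star_time(s, 0.55)),
               logical(1))
  host <- host[ok]; spans <- spans[ok]
  len <- vapply(spans, function(s) s[2] - s[1], double(1))
  # one star midway on every eligible branch, then a second on the longest
  stars <- tibble::tibble(host = host,
                          t = vapply(spans, star_time, double(1), f = 0.55))
  need <- 51 - nrow(stars)
  if (need > 0) {
    second <- vapply(spans, star_time, double(1), f = 0.85)
    extra <- order(len, decreasing = TRUE)
    extra <- extra[!is.na(second[extra])][seq_len(need)]
    stars <- dplyr::bind_rows(stars,
                              tibble::tibble(host = host[extra], t = second[extra]))
  }
  stars <- stars[seq_len(51), ]

  size_of <- stats::setNames(sc$populations$size, sc$populations$name)
  new_pops <- list(); new_splits <- list(); new_merges <- list()
  for (i in seq_len(nrow(stars))) {
    h <- stars$host[i]; t1 <- stars$t[i]
    s <- sprintf("S%02d", i)
    a <- sprintf("x%02da", i); b <- sprintf("x%02db", i)
    new_pops[[i]] <- tibble::tibble(
      name = c(s, a, b), size = size_of[[h]],
      samples = c(0L, 10L, 10L),
      label = c(s, paste0("e", i, "a"), paste0("e", i, "b")))
    new_splits[[i]] <- tibble::tibble(time = t1 - 50,
                                      derived = list(c(a, b)), ancestral = s)
    new_merges[[i]] <- tibble::tibble(time = t1, derived = s, into = h)
  }
  sc$populations <- dplyr::bind_rows(sc$populations, dplyr::bind_rows(new_pops))
  sc$splits <- dplyr::bind_rows(sc$splits, dplyr::bind_rows(new_splits))
  sc$merges <- dplyr::bind_rows(sc$merges, dplyr::bind_rows(new_merges))
  sc$name <- "many_pops_tree"
  validate_scenario(sc)
}

#' Standard tree with a pulse at generation 240 followed by continuous flow
#'
#' Moves the admixture pulse that forms population 14 to generation 240,
#' immediately after the pulse donor's split from the population-5 lineage at
#' generation 250, and adds continuous migration from populations 5 and 9
#' into population 14 at per-generation rate `m` from the pulse to the
#' present.
#'
#' @inheritParams build_standard_tree
#' @param m Per-generation migration rate from each of populations 5 and 9
#'   into population 14.
#' @return A [demography_scenario()].
#' @export
build_continuous_after_pulse <- function(alpha = 0.5, m = 0) {
  stopifnot(m >= 0, m <= 1)
  sc <- build_standard_tree(alpha)
  sc$admixtures$time[sc$admixtures$derived == "p14"] <- 240
  if (m > 0) {
    sc$migrations <- tibble::tibble(
      donor = c("p5", "p9"), recipient = "p14", rate = m,
      start = 0, end = 240)
  }
  sc$name <- sprintf("continuous_after_pulse_a%.3g_m%g", alpha, m)
  sc
}

#' Stepping-stone scenario
#'
#' Six demes (effective size 5,000) split simultaneously from a common
#' ancestor 1,000 generations ago and thereafter exchange migrants between
#' chain neighbors at per-generation rate `m`; three outgroup populations are
#' symmetrically related to the demes, with all nine lineages descending from
#' a common ancestor 2,000 generations ago. Population labels: demes
#' `"0"`-`"5"`, outgroups `"6"`-`"8"`.
#'
#' @param m Neighbor migration rate per generation (0.01 with Ne 5,000 is 100
#'   migrants per generation).
#' @param ne Effective size of every branch (default 5,000).
#' @return A [demography_scenario()].
#' @export
build_stepping_stone <- function(m = 0.01, ne = 5000) {
  stopifnot(m >= 0)
  demes <- paste0("d", 0:5)
  outs <- paste0("o", 6:8)
  pops <- tibble::tibble(
    name = c(demes, outs, "DANC", "ROOT"),
    size = ne,
    samples = c(rep(10L, 9), 0L, 0L),
    label = c(as.character(0:8), "DANC", "ROOT"))
  splits <- tibble::tibble(
    time = c(1000, 2000),
    derived = list(demes, c("DANC", outs)),
    ancestral = c("DANC", "ROOT"))
  migrations <- NULL
  if (m > 0) {
    nb <- tibble::tibble(a = demes[-6], b = demes[-1])
    migrations <- tibble::tibble(
      donor = c(nb$a, nb$b), recipient = c(nb$b, nb$a),
      rate = m, start = 0, end = 1000)
  }
  demography_scenario(sprintf("stepping_stone_m%g", m), pops,
                      splits = splits, migrations = migrations)
}

#' Restrict which populations are sampled
#'
#' Sets the sample count of all sampled populations not listed to zero.
#' Simulating only the populations a given analysis needs reduces cost;
#' the marginal genealogy of the retained populations is unchanged.
#'
#' @param sc A [demography_scenario()].
#' @param labels Output labels of populations to keep sampling.
#' @return A [demography_scenario()].
#' @export
restrict_samples <- function(sc, labels) {
  drop_ <- !(sc$populations$label %in% as.character(labels))
  sc$populations$samples[drop_ & !is.na(sc$populations$samples)] <- 0L
  sc
}
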