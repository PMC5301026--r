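# Structured-coalescent scenario machinery. Sizes in the public interface are
# diploid individuals (N); the simulator works in gene copies (2N for nuclear
# microsatellites, N for the haploid chloroplast locus). Times are generations
# backward from the present. Events with tied times are applied in list order.

.ev_type <- c(size_change = 0L, merge = 1L, migration = 2L)

#' Construct a demographic scenario specification
#'
#' @param demes data frame with columns `label` and `size` (present-day
#'   effective size, diploid individuals).
#' @param events data frame with columns `time` (generations backward, > 0),
#'   `type` (`"size_change"`, `"merge"`, `"migration"`), `a` (focal deme
#'   label), `b` (merge target label or `NA`), `x` (new size / new rate).
#' @param migration per-pair backward migration rate active from the present
#'   until changed by a `migration` event, in `[0, 1]`.
#' @param n_msat,mu_msat number of microsatellite loci and their per-locus
#'   per-generation stepwise mutation rate.
#' @param n_seq,mu_seq number of haploid sequence loci and their per-locus
#'   infinite-sites mutation rate.
#' @param kind free-text scenario tag.
#' @param params optional named vector of the generating parameters (kept for
#'   ABC bookkeeping).
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(demes, events, migration, n_msat = 11L,
                          mu_msat = 5e-4, n_seq = 1L, mu_seq = 1e-4,
                          kind = "custom", params = NULL) {
  stopifnot(is.data.frame(demes), all(c("label", "size") %in% names(demes)))
  if (nrow(demes) < 1L) stop("scenario needs at least one deme")
  if (anyDuplicated(demes$label)) stop("deme labels must be unique")
  if (any(demes$size < 1)) stop("all deme sizes must be >= 1")
  if (migration < 0 || migration > 1) stop("migration rate must lie in [0, 1]")
  if (is.null(events) || nrow(events) == 0L) {
    events <- data.frame(time = numeric(), type = character(),
                         a = character(), b = character(), x = numeric())
  }
  if (nrow(events)) {
    if (any(events$time <= 0)) stop("event times must be positive")
    if (is.unsorted(events$time)) stop("event times must be ordered")
    if (!all(events$type %in% names(.ev_type))) stop("unknown event type")
    bad <- !(events$a %in% demes$label)
    if (any(bad)) stop("event refers to unknown deme: ", events$a[bad][1L])
    mg <- events$type == "merge"
    if (any(mg & !(events$b %in% demes$label))) stop("merge target unknown")
    if (any(events$type == "size_change" & events$x < 1))
      stop("size change below one individual")
  }
  # every deme must fold into a single ancestral lineage
  if (nrow(demes) > 1L) {
    alive <- demes$label
    for (i in seq_len(nrow(events))) {
      if (events$type[i] == "merge" && events$a[i] %in% alive &&
          events$b[i] %in% alive)
        alive <- setdiff(alive, events$a[i])
    }
    if (length(alive) != 1L)
      stop("scenario invalid: demes never merge into a single ancestor (",
           paste(alive, collapse = ","), " remain)")
  }
  structure(list(demes = demes, events = events, migration = migration,
                 n_msat = as.integer(n_msat), mu_msat = mu_msat,
                 n_seq = as.integer(n_seq), mu_seq = mu_seq,
                 kind = kind, params = params),
            class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat("scenario_spec <", x$kind, ">: ", nrow(x$demes), " demes, ",
      nrow(x$events), " events, m = ", signif(x$migration, 3), "\n", sep = "")
  invisible(x)
}

.ev <- function(time, type, a, b = NA_character_, x = NA_real_)
  data.frame(time = time, type = type, a = a, b = b, x = x,
             stringsAsFactors = FALSE)

#' Secondary-contact scenario: old divergence, bottlenecks, recent gene flow
#'
#' Two lineages (`bar`, `tpe`) split anciently at `t_div` from an ancestor of
#' size `N_anc`; each passes a bottleneck; migration at rate `m` is active
#' only more recently than `t_contact` (the secondary-contact onset).
#'
#' @param N_anc ancestral size; `N_bar`, `N_tpe` present sizes;
#'   `N_bar_bot`, `N_tpe_bot` bottleneck sizes entered (backward) at
#'   `t_bot_bar`, `t_bot_tpe`.
#' @param t_contact migration onset (generations backward); must be `< t_div`.
#' @param t_div divergence time.
#' @param m per-pair migration rate during the contact phase.
#' @inheritParams scenario_spec
#' @return A [scenario_spec()].
#' @export
scenario_secondary_contact <- function(N_anc, N_bar, N_tpe, N_bar_bot,
                                       N_tpe_bot, t_bot_bar, t_bot_tpe,
                                       t_contact, t_div, m,
                                       n_msat = 11L, mu_msat = 5e-4,
                                       n_seq = 1L, mu_seq = 1e-4) {
  if (t_contact >= t_div)
    stop("secondary-contact onset must predate (be more recent than) the divergence time")
  if (t_bot_bar >= t_div || t_bot_tpe >= t_div)
    stop("bottlenecks must be more recent than the divergence time")
  ev <- rbind(.ev(t_contact, "migration", "bar", x = 0),
              .ev(t_bot_bar, "size_change", "bar", x = N_bar_bot),
              .ev(t_bot_tpe, "size_change", "tpe", x = N_tpe_bot),
              .ev(t_div, "merge", "tpe", "bar"),
              .ev(t_div, "size_change", "bar", x = N_anc))
  ev <- ev[order(ev$time), ]
  scenario_spec(data.frame(label = c("bar", "tpe"), size = c(N_bar, N_tpe)),
                ev, migration = m, n_msat = n_msat, mu_msat = mu_msat,
                n_seq = n_seq, mu_seq = mu_seq, kind = "secondary_contact",
                params = c(N_anc = N_anc, N_bar = N_bar, N_tpe = N_tpe,
                           N_bar_bot = N_bar_bot, N_tpe_bot = N_tpe_bot,
                           t_bot_bar = t_bot_bar, t_bot_tpe = t_bot_tpe,
                           t_contact = t_contact, t_div = t_div, m = m,
                           mu = mu_msat))
}

#' Founder-speciation scenario: tpe recently founded from bar
#'
#' Backward in time: `bar` has present size `N_B` until `t_recover`, sits at
#' the bottleneck size `N_Bp` over `[t_recover, T1)`, and has ancestral size
#' `N_A` beyond `T1` (the colonization/coalescent time of `bar`). `tpe` is
#' founded from `bar` at `T2 < T1` with size `N_T`; symmetric migration `m`
#' runs continuously since the founding.
#'
#' @param N_A,N_Bp,N_B,N_T sizes (diploid individuals).
#' @param T1,T2 times (generations backward), `T2 < T1`.
#' @param m per-pair migration rate since the founding.
#' @param t_recover time the bottleneck ends looking backward (default `T2`).
#' @inheritParams scenario_spec
#' @return A [scenario_spec()].
#' @export
scenario_founder <- function(N_A, N_Bp, N_B, N_T, T1, T2, m,
                             t_recover = T2, n_msat = 11L, mu_msat = 5e-4,
                             n_seq = 1L, mu_seq = 1e-4) {
  if (T2 >= T1) stop("founding time T2 must be more recent than T1")
  if (t_recover > T1) stop("bottleneck recovery cannot predate T1")
  ev <- rbind(.ev(T2, "merge", "tpe", "bar"),
              .ev(T2, "migration", "bar", x = 0),
              .ev(t_recover, "size_change", "bar", x = N_Bp),
              .ev(T1, "size_change", "bar", x = N_A))
  ev <- ev[order(ev$time), ]
  scenario_spec(data.frame(label = c("bar", "tpe"), size = c(N_B, N_T)),
                ev, migration = m, n_msat = n_msat, mu_msat = mu_msat,
                n_seq = n_seq, mu_seq = mu_seq, kind = "founder",
                params = c(N_A = N_A, N_Bp = N_Bp, N_B = N_B, N_T = N_T,
                           T1 = T1, T2 = T2, m = m, mu = mu_msat))
}

#' Multiple-origins scenario: three independent foundings of tpe from bar
#'
#' Four demes (`bar`, `tpe1`..`tpe3`); each tpe deme merges independently into
#' `bar` at its own founding time. Migration is a free parameter, symmetric
#' among open demes for the whole history.
#'
#' @param N_B,N_T1,N_T2,N_T3 present sizes; `N_A` ancestral size of `bar`
#'   beyond the oldest founding (defaults to `N_B`).
#' @param T_1,T_2,T_3 founding times of the three tpe demes.
#' @param m per-pair migration rate.
#' @inheritParams scenario_spec
#' @return A [scenario_spec()].
#' @export
scenario_multiple_origins <- function(N_B, N_T1, N_T2, N_T3, T_1, T_2, T_3, m,
                                      N_A = N_B, n_msat = 11L, mu_msat = 5e-4,
                                      n_seq = 1L, mu_seq = 1e-4) {
  ev <- rbind(.ev(T_1, "merge", "tpe1", "bar"),
              .ev(T_2, "merge", "tpe2", "bar"),
              .ev(T_3, "merge", "tpe3", "bar"),
              .ev(max(T_1, T_2, T_3), "size_change", "bar", x = N_A))
  ev <- ev[order(ev$time), ]
  scenario_spec(data.frame(label = c("bar", "tpe1", "tpe2", "tpe3"),
                           size = c(N_B, N_T1, N_T2, N_T3)),
                ev, migration = m, n_msat = n_msat, mu_msat = mu_msat,
                n_seq = n_seq, mu_seq = mu_seq, kind = "multiple_origins",
                params = c(N_B = N_B, N_T1 = N_T1, N_T2 = N_T2, N_T3 = N_T3,
                           T_1 = T_1, T_2 = T_2, T_3 = T_3, m = m,
                           mu = mu_msat))
}

#' Single-origin scenario: one founding of tpe followed by internal splits
#'
#' `tpe1` is founded from `bar` at `T_found`; `tpe2` and `tpe3` split from
#' `tpe1` at `t_split2`, `t_split3`, both more recent than the founding.
#'
#' @param N_B,N_T1,N_T2,N_T3 present sizes; `N_A` ancestral size of `bar`.
#' @param T_found founding time of the tpe lineage.
#' @param t_split2,t_split3 within-tpe split times (`< T_found`).
#' @param m per-pair migration rate.
#' @inheritParams scenario_spec
#' @return A [scenario_spec()].
#' @export
scenario_single_origin <- function(N_B, N_T1, N_T2, N_T3, T_found, t_split2,
                                   t_split3, m, N_A = N_B, n_msat = 11L,
                                   mu_msat = 5e-4, n_seq = 1L, mu_seq = 1e-4) {
  if (t_split2 >= T_found || t_split3 >= T_found)
    stop("within-tpe split times must be more recent than the founding time")
  ev <- rbind(.ev(t_split2, "merge", "tpe2", "tpe1"),
              .ev(t_split3, "merge", "tpe3", "tpe1"),
              .ev(T_found, "merge", "tpe1", "bar"),
              .ev(T_found, "size_change", "bar", x = N_A))
  ev <- ev[order(ev$time), ]
  scenario_spec(data.frame(label = c("bar", "tpe1", "tpe2", "tpe3"),
                           size = c(N_B, N_T1, N_T2, N_T3)),
                ev, migration = m, n_msat = n_msat, mu_msat = mu_msat,
                n_seq = n_seq, mu_seq = mu_seq, kind = "single_origin",
                params = c(N_B = N_B, N_T1 = N_T1, N_T2 = N_T2, N_T3 = N_T3,
                           T_found = T_found, t_split2 = t_split2,
                           t_split3 = t_split3, m = m, mu = mu_msat))
}

#' Island-model scenario (constant-size demes, symmetric migration)
#'
#' Used as the null model of the Fdist outlier scan; a nominal ancestral merge
#' far in the past closes the genealogy.
#'
#' @param n_demes number of demes.
#' @param N deme size (diploid individuals).
#' @param m per-pair migration rate.
#' @inheritParams scenario_spec
#' @return A [scenario_spec()].
#' @export
scenario_island <- function(n_demes, N, m, n_msat = 1L, mu_msat = 5e-4,
                            n_seq = 0L, mu_seq = 0) {
  labels <- paste0("deme", seq_len(n_demes))
  t_anc <- 400 * N  # effectively never reached when migration connects demes
  ev <- do.call(rbind, lapply(labels[-1L], function(l)
    .ev(t_anc, "merge", l, labels[1L])))
  scenario_spec(data.frame(label = labels, size = rep(N, n_demes)),
                ev, migration = m, n_msat = n_msat, mu_msat = mu_msat,
                n_seq = n_seq, mu_seq = mu_seq, kind = "island",
                params = c(n_demes = n_demes, N = N, m = m, mu = mu_msat))
}

# ---- simulation --------------------------------------------------------------

.events_to_matrix <- function(spec, copy_factor) {
  demes <- spec$demes$label
  ev <- spec$events
  if (nrow(ev) == 0L) return(matrix(numeric(), 0L, 5L))
  m <- matrix(0, nrow(ev), 5L)
  m[, 1L] <- ev$time
  m[, 2L] <- .ev_type[ev$type]
  m[, 3L] <- match(ev$a, demes) - 1L
  m[, 4L] <- ifelse(is.na(ev$b), 0, match(ev$b, demes) - 1L)
  m[, 5L] <- ifelse(ev$type == "size_change", ev$x * copy_factor,
                    ifelse(ev$type == "migration", ev$x, 0))
  m
}

#' Simulate one locus under a scenario (instrumented low level)
#'
#' Returns the raw per-gene-copy output plus the realized total branch length
#' and mutation count of the genealogy — the hook used to check that mutation
#' counts are Poisson with mean `mu * tree length`.
#'
#' @param spec a [scenario_spec()].
#' @param copies_per_deme integer vector of sampled gene copies per deme (in
#'   `spec$demes` order).
#' @param mu per-locus per-generation mutation rate.
#' @param model `"smm"` (stepwise microsatellite) or `"infinite_sites"`.
#' @param ploidy 2 for nuclear loci, 1 for the haploid chloroplast locus
#'   (scales sizes to gene copies).
#' @param ancestral_allele root repeat score for SMM loci.
#' @return List with `alleles` (SMM) or `genotypes` (0/1 matrix, infinite
#'   sites), `tree_length`, `n_mutations`, `deme` (per copy).
#' @export
simulate_locus <- function(spec, copies_per_deme, mu,
                           model = c("smm", "infinite_sites"), ploidy = 2L,
                           ancestral_allele = 200L) {
  model <- match.arg(model)
  stopifnot(inherits(spec, "scenario_spec"))
  nd <- nrow(spec$demes)
  if (length(copies_per_deme) != nd) stop("one sample size per deme required")
  if (any(copies_per_deme < 0) || sum(copies_per_deme) < 1)
    stop("need at least one sampled gene copy")
  if (sum(copies_per_deme) > 10000L) stop("sample size exceeds configured cap (10,000 copies)")
  deme0 <- rep(seq_len(nd) - 1L, copies_per_deme)
  res <- .sim_locus_cpp(as.integer(deme0),
                        as.numeric(spec$demes$size * ploidy),
                        .events_to_matrix(spec, ploidy),
                        spec$migration, mu,
                        if (model == "smm") 0L else 1L,
                        as.integer(ancestral_allele))
  res$deme <- spec$demes$label[deme0 + 1L]
  res
}

#' Simulate a full dataset (microsatellites + optional sequences)
#'
#' Draws independent gene genealogies per locus under the structured
#' coalescent of `spec`, mutates microsatellite loci by the strict symmetric
#' single-step model and sequence loci by infinite sites, and packages the
#' result as a [genotype_table()] plus (optionally) a [seq_alignment()].
#' Deterministic for a fixed seed.
#'
#' @param spec a [scenario_spec()].
#' @param sample_sizes named integer vector: diploid individuals per deme
#'   (names matching `spec$demes$label`). Sequence loci sample one haploid
#'   copy per individual.
#' @param seed optional integer seed (`set.seed` is called when supplied).
#' @return List of class `sim_dataset`: `genotypes`, `sequences` (or `NULL`),
#'   `seed`, `scenario`.
#' @export
simulate_coalescent <- function(spec, sample_sizes, seed = NULL) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (!is.null(seed)) set.seed(seed)
  labels <- spec$demes$label
  if (is.null(names(sample_sizes))) names(sample_sizes) <- labels
  if (!setequal(names(sample_sizes), labels))
    stop("sample sizes must name every scenario deme")
  n_ind <- as.integer(sample_sizes[labels])
  if (any(n_ind < 1L)) stop("need at least one individual per deme")

  demes_ind <- rep(labels, n_ind)
  ids <- paste0(demes_ind, "_", unlist(lapply(n_ind, seq_len)))
  n_tot <- sum(n_ind)

  a1 <- a2 <- matrix(NA_integer_, n_tot, spec$n_msat)
  for (l in seq_len(spec$n_msat)) {
    r <- simulate_locus(spec, 2L * n_ind, spec$mu_msat, "smm", ploidy = 2L)
    al <- r$alleles
    a1[, l] <- al[seq(1L, 2L * n_tot, by = 2L)]
    a2[, l] <- al[seq(2L, 2L * n_tot, by = 2L)]
  }
  gt <- genotype_table(ids, demes_ind, sprintf("L%02d", seq_len(spec$n_msat)),
                       a1, a2)

  aln <- NULL
  if (spec$n_seq > 0L) {
    segs <- lapply(seq_len(spec$n_seq), function(l)
      simulate_locus(spec, n_ind, spec$mu_seq, "infinite_sites", ploidy = 1L))
    # one invariant backbone column per locus, then the segregating columns
    seqs <- vapply(seq_len(n_tot), function(i) {
      paste(vapply(segs, function(sg) {
        g <- sg$genotypes
        paste0("A", paste(c("A", "T")[g[i, ] + 1L], collapse = ""))
      }, character(1L)), collapse = "")
    }, character(1L))
    aln <- seq_alignment(ids, demes_ind, seqs)
  }
  structure(list(genotypes = gt, sequences = aln, seed = seed,
                 scenario = spec), class = "sim_dataset")
}

# ---- priors ------------------------------------------------------------------

#' Default ABC prior specification for a scenario family
#'
#' Log-uniform envelopes: sizes N in `[10, 1e4]` individuals, times in
#' `[1, 1e5]` generations, migration in `[1e-6, 1e-2]` per pair per
#' generation, mutation rate in `[1e-5, 1e-3]` per locus per generation.
#' Order constraints (e.g. `T2 < T1`) are enforced by rejection at draw time.
#'
#' @param kind one of `"secondary_contact"`, `"founder"`,
#'   `"multiple_origins"`, `"single_origin"`.
#' @return Named list of `c(lo, hi)` log-uniform bounds per parameter.
#' @export
default_priors <- function(kind = c("secondary_contact", "founder",
                                    "multiple_origins", "single_origin")) {
  kind <- match.arg(kind)
  N <- c(10, 1e4); Tt <- c(1, 1e5); m <- c(1e-6, 1e-2); mu <- c(1e-5, 1e-3)
  switch(kind,
    secondary_contact = list(N_anc = N, N_bar = N, N_tpe = N, N_bar_bot = N,
                             N_tpe_bot = N, t_bot_bar = Tt, t_bot_tpe = Tt,
                             t_contact = Tt, t_div = Tt, m = m, mu = mu),
    founder = list(N_A = N, N_Bp = N, N_B = N, N_T = c(10, 1e3), T1 = Tt,
                   T2 = Tt, m = m, mu = mu),
    multiple_origins = list(N_B = N, N_T1 = c(10, 1e3), N_T2 = c(10, 1e3),
                            N_T3 = c(10, 1e3), T_1 = Tt, T_2 = Tt, T_3 = Tt,
                            m = m, mu = mu),
    single_origin = list(N_B = N, N_T1 = c(10, 1e3), N_T2 = c(10, 1e3),
                         N_T3 = c(10, 1e3), T_found = Tt, t_split2 = Tt,
                         t_split3 = Tt, m = m, mu = mu))
}

.rlogunif <- function(n, lo, hi) exp(runif(n, log(lo), log(hi)))

#' Draw a scenario from its prior
#'
#' Samples each parameter log-uniformly within its prior bounds, applies the
#' scenario's order constraints by rejection, and returns a validated
#' [scenario_spec()] whose `params` records the draw.
#'
#' @param kind scenario family (see [default_priors()]).
#' @param priors prior list, defaulting to [default_priors()].
#' @param n_msat,n_seq locus counts passed to the constructor.
#' @param max_tries rejection budget for order constraints.
#' @return A [scenario_spec()].
#' @export
draw_scenario <- function(kind, priors = default_priors(kind), n_msat = 11L,
                          n_seq = 1L, max_tries = 1000L) {
  for (i in seq_len(max_tries)) {
    p <- vapply(priors, function(b) .rlogunif(1L, b[1L], b[2L]), numeric(1L))
    ok <- switch(kind,
      secondary_contact = p["t_contact"] < p["t_div"] &&
        p["t_bot_bar"] < p["t_div"] && p["t_bot_tpe"] < p["t_div"],
      founder = p["T2"] < p["T1"],
      multiple_origins = TRUE,
      single_origin = p["t_split2"] < p["T_found"] &&
        p["t_split3"] < p["T_found"],
      stop("unknown scenario kind: ", kind))
    if (!ok) next
    spec <- switch(kind,
      secondary_contact = scenario_secondary_contact(
        p["N_anc"], p["N_bar"], p["N_tpe"], p["N_bar_bot"], p["N_tpe_bot"],
        p["t_bot_bar"], p["t_bot_tpe"], p["t_contact"], p["t_div"], p["m"],
        n_msat = n_msat, mu_msat = p["mu"], n_seq = n_seq, mu_seq = p["mu"]),
      founder = scenario_founder(
        p["N_A"], p["N_Bp"], p["N_B"], p["N_T"], p["T1"], p["T2"], p["m"],
        n_msat = n_msat, mu_msat = p["mu"], n_seq = n_seq, mu_seq = p["mu"]),
      multiple_origins = scenario_multiple_origins(
        p["N_B"], p["N_T1"], p["N_T2"], p["N_T3"], p["T_1"], p["T_2"],
        p["T_3"], p["m"], n_msat = n_msat, mu_msat = p["mu"], n_seq = n_seq,
        mu_seq = p["mu"]),
      single_origin = scenario_single_origin(
        p["N_B"], p["N_T1"], p["N_T2"], p["N_T3"], p["T_found"],
        p["t_split2"], p["t_split3"], p["m"], n_msat = n_msat,
        mu_msat = p["mu"], n_seq = n_seq, mu_seq = p["mu"]))
    spec$params <- p
    return(spec)
  }
  stop("could not satisfy scenario constraints in ", max_tries, " draws")
}
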