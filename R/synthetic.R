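#' Synthetic longitudinal EHR configuration
#'
#' The generator emulates the structural features that motivate
#' time-sensitive context selection: care arrives in *episodes* — bursts of
#' closely spaced visits (days apart) separated by long quiet gaps (months)
#' — and each episode is driven by one latent condition, so clinically
#' related codes co-occur within an episode while codes from different
#' episodes of the same patient are temporally far apart. Background noise
#' codes (medications and procedures) appear throughout.
#'
#' The default gap distributions (intra-episode 1–10 days, inter-episode
#' 60–400 days) guarantee that no two visits in *different* episodes of a
#' patient are within 30 days of each other, so a 30-day time window
#' provably never mixes episodes while a fixed token window does.
#'
#' @param n_patients Number of patients (default 2000).
#' @param n_groups Latent concept groups (default 10).
#' @param codes_per_group Diagnosis codes per group (default 20).
#' @param background_codes Number of noise codes (default 20; half
#'   medications, half procedures).
#' @param episodes_mean Mean episodes per patient (1 + Poisson; default 3).
#' @param visits_per_episode_mean Mean visits per episode (1 + Poisson;
#'   default 3).
#' @param events_per_visit_mean Mean coded events per visit (1 + Poisson;
#'   default 5).
#' @param intra_gap_range Integer day-gap range between consecutive visits
#'   of one episode (uniform; default `c(1, 10)`).
#' @param inter_gap_range Integer day-gap range between the last visit of an
#'   episode and the first of the next (uniform; default `c(60, 400)`).
#' @param noise_rate Probability that a drawn event is a background code
#'   (default 0.1).
#' @param shared_prefix If `TRUE` (default), the codes of group `g` share
#'   the 3-character ICD prefix `100 + g` (e.g. `101.01 .. 101.20`), so the
#'   built-in ICD-prefix grouping recovers the ground truth and subword
#'   models can exploit the prefix.
#' @param start_date_range Calendar window the first visit of each patient
#'   is drawn from.
#' @param seed Integer seed; the whole corpus is a deterministic function of
#'   the config.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_patients = 2000L, n_groups = 10L,
                         codes_per_group = 20L, background_codes = 20L,
                         episodes_mean = 3, visits_per_episode_mean = 3,
                         events_per_visit_mean = 5,
                         intra_gap_range = c(1L, 10L),
                         inter_gap_range = c(60L, 400L),
                         noise_rate = 0.1, shared_prefix = TRUE,
                         start_date_range = as.Date(c("2000-01-01",
                                                      "2010-12-31")),
                         seed = 1L) {
  if (n_patients < 0) stop("n_patients must be >= 0")
  if (n_groups < 1 || codes_per_group < 1) {
    stop("need at least one group and one code per group")
  }
  if (episodes_mean <= 0 || visits_per_episode_mean <= 0 ||
      events_per_visit_mean <= 0) {
    stop("all means must be positive")
  }
  if (noise_rate < 0 || noise_rate >= 1) stop("noise_rate must be in [0, 1)")
  if (noise_rate > 0 && background_codes < 1) {
    stop("noise_rate > 0 requires background codes")
  }
  if (max(intra_gap_range) >= min(inter_gap_range)) {
    stop("intra-episode gaps must all be shorter than every inter-episode ",
         "gap (this separation is what makes time windows informative)")
  }
  structure(list(n_patients = as.integer(n_patients),
                 n_groups = as.integer(n_groups),
                 codes_per_group = as.integer(codes_per_group),
                 background_codes = as.integer(background_codes),
                 episodes_mean = episodes_mean,
                 visits_per_episode_mean = visits_per_episode_mean,
                 events_per_visit_mean = events_per_visit_mean,
                 intra_gap_range = as.integer(intra_gap_range),
                 inter_gap_range = as.integer(inter_gap_range),
                 noise_rate = noise_rate,
                 shared_prefix = isTRUE(shared_prefix),
                 start_date_range = as.Date(start_date_range),
                 seed = as.integer(seed)),
            class = "synth_config")
}

synth_group_codes <- function(config) {
  lapply(seq_len(config$n_groups), function(g) {
    if (config$shared_prefix) {
      render_token("D", sprintf("%d.%02d", 100L + g,
                                seq_len(config$codes_per_group)))
    } else {
      render_token("D", sprintf("%d", 1000L + (g - 1L) *
                                  config$codes_per_group +
                                  seq_len(config$codes_per_group)))
    }
  })
}

synth_background_codes <- function(config) {
  nb <- config$background_codes
  if (nb == 0L) return(character(0))
  n_m <- ceiling(nb / 2)
  c(render_token("M", sprintf("drug%02d", seq_len(n_m))),
    render_token("P", sprintf("proc%02d", seq_len(nb - n_m))))
}

#' Generate a synthetic corpus with ground-truth grouping
#'
#' Each patient draws a number of episodes; each episode is assigned one
#' latent group uniformly at random and contributes a run of closely spaced
#' visits. Each visit draws its events from the episode group's codes with
#' probability `1 - noise_rate`, otherwise from the background codes;
#' duplicates within a visit collapse (events are a set). Visit dates
#' accumulate intra- and inter-episode gaps. Byte-identical output for a
#' given config.
#'
#' @param config A [synth_config()].
#' @return List with `corpus` (an `ehr_corpus`), `grouping` (named character
#'   vector: every group code token -> its group label `"G01"` ...;
#'   background codes unmapped) and `episode_ids` (per patient, the episode
#'   number of each visit — ground truth for context diagnostics).
#' @export
generate_corpus <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  group_codes <- synth_group_codes(config)
  bg_codes <- synth_background_codes(config)
  group_labels <- sprintf("G%02d", seq_len(config$n_groups))
  grouping <- setNames(rep(group_labels, lengths(group_codes)),
                       unlist(group_codes, use.names = FALSE))

  with_seed(config$seed, {
    records <- vector("list", config$n_patients)
    episode_ids <- vector("list", config$n_patients)
    day0 <- as.numeric(config$start_date_range[1L])
    day_span <- as.numeric(diff(config$start_date_range))
    for (p in seq_len(config$n_patients)) {
      n_ep <- 1L + rpois(1L, config$episodes_mean - 1)
      day <- day0 + floor(runif(1L, 0, day_span + 1))
      visits <- list()
      ep_of_visit <- integer(0)
      for (ep in seq_len(n_ep)) {
        g <- sample.int(config$n_groups, 1L)
        n_vis <- 1L + rpois(1L, config$visits_per_episode_mean - 1)
        for (vs in seq_len(n_vis)) {
          if (vs > 1L) {
            day <- day + sample(seq.int(config$intra_gap_range[1L],
                                        config$intra_gap_range[2L]), 1L)
          }
          n_ev <- 1L + rpois(1L, config$events_per_visit_mean - 1)
          is_bg <- runif(n_ev) < config$noise_rate
          ev <- character(n_ev)
          if (any(!is_bg)) {
            ev[!is_bg] <- sample(group_codes[[g]], sum(!is_bg),
                                 replace = TRUE)
          }
          if (any(is_bg)) {
            ev[is_bg] <- sample(bg_codes, sum(is_bg), replace = TRUE)
          }
          visits[[length(visits) + 1L]] <-
            new_visit(sprintf("p%05d_v%03d", p, length(visits) + 1L),
                      as.Date(day, origin = "1970-01-01"), ev)
          ep_of_visit <- c(ep_of_visit, ep)
        }
        if (ep < n_ep) {
          day <- day + sample(seq.int(config$inter_gap_range[1L],
                                      config$inter_gap_range[2L]), 1L)
        }
      }
      records[[p]] <- new_patient_record(sprintf("p%05d", p), visits)
      episode_ids[[p]] <- ep_of_visit
    }
    list(corpus = new_corpus(records), grouping = grouping,
         episode_ids = episode_ids)
  })
}

#' Summary statistics of a corpus
#'
#' @param corpus An `ehr_corpus`.
#' @return List with `n_patients`, `n_visits`, `n_events` (distinct per
#'   visit, summed), `vocabulary_size` and `gap_histogram` (a table of
#'   consecutive-visit day gaps).
#' @export
corpus_stats <- function(corpus) {
  n_visits <- vapply(corpus$records, function(r) length(r$visits), 0L)
  n_events <- vapply(corpus$records, record_epsilon, 0L)
  gaps <- unlist(lapply(corpus$records, function(r) {
    d <- as.numeric(as.Date(vapply(r$visits,
                                   function(v) as.character(v$date), "")))
    diff(d)
  }), use.names = FALSE)
  list(n_patients = length(corpus$records),
       n_visits = sum(n_visits),
       n_events = sum(n_events),
       vocabulary_size = nrow(corpus$vocabulary),
       gap_histogram = table(gaps))
}
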