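## Small in-code fixtures used across test files.

## One wound row in the cohort schema.
make_row <- function(wound_id, patient_id = wound_id,
                     skin_type = "hair_bearing",
                     g1 = c(0, 0, 0, 0), g2 = g1,
                     judgment = "superficial",
                     outcome = "healed_spontaneously",
                     days = NA_integer_) {
  data.frame(
    wound_id = wound_id, patient_id = patient_id, skin_type = skin_type,
    surf1 = g1[1], epi1 = g1[2], dermal1 = g1[3], vasc1 = g1[4],
    surf2 = g2[1], epi2 = g2[2], dermal2 = g2[3], vasc2 = g2[4],
    clinical_judgment = judgment, outcome = outcome,
    days_to_graft = days, stringsAsFactors = FALSE
  )
}

## Ten wounds with known scores and outcomes, for enumeration oracles.
## Scores: 0,2,3,3,4,4,5,5,6,6; deep course for the last three.
ten_wound_cohort <- function() {
  rows <- list(
    make_row("w01", g1 = c(0, 0, 0, 0)),
    make_row("w02", g1 = c(1, 1, 0, 0)),
    make_row("w03", g1 = c(1, 0, 2, 0)),
    make_row("w04", g1 = c(0, 1, 1, 1), skin_type = "glabrous"),
    make_row("w05", g1 = c(1, 1, 1, 1)),
    make_row("w06", g1 = c(1, 1, 0, 2), skin_type = "glabrous"),
    make_row("w07", g1 = c(1, 1, 2, 1)),            # score 5, healed
    make_row("w08", g1 = c(1, 0, 2, 2), outcome = "grafted",
             days = 9L, judgment = "deep"),          # score 5, grafted
    make_row("w09", g1 = c(1, 1, 2, 2), outcome = "grafted",
             days = 11L, judgment = "deep"),         # score 6, grafted
    make_row("w10", g1 = c(1, 1, 2, 2),
             outcome = "deep_refused_graft", judgment = "deep")
  )
  do.call(rbind, rows)
}

## Brute-force confusion counts: direct enumeration over records.
oracle_confusion <- function(cohort, threshold = 4L,
                             deep_rule = "graft_or_refused") {
  a <- b <- c_ <- d <- 0L
  for (i in seq_len(nrow(cohort))) {
    r <- cohort[i, ]
    s <- r$surf1 + r$epi1 + r$dermal1 + r$vasc1
    pred_deep <- s > threshold
    act_deep <- if (deep_rule == "grafted_only") {
      r$outcome == "grafted"
    } else {
      r$outcome %in% c("grafted", "deep_refused_graft")
    }
    if (pred_deep && act_deep) a <- a + 1L
    else if (pred_deep && !act_deep) b <- b + 1L
    else if (!pred_deep && act_deep) c_ <- c_ + 1L
    else d <- d + 1L
  }
  c(a = a, b = b, c = c_, d = d)
}

## Exact binomial CI endpoints by tail inversion on a fine grid of p:
## lower = smallest p with P(X >= x) >= alpha/2, upper = largest p with
## P(X <= x) >= alpha/2. Independent of the qbeta route in the package.
oracle_exact_ci <- function(x, n, conf = 0.95, step = 1e-6) {
  alpha <- 1 - conf
  grid <- seq(0, 1, by = step)
  lo <- if (x == 0) 0 else {
    upper_tail <- 1 - stats::pbinom(x - 1, n, grid)
    grid[which(upper_tail >= alpha / 2)[1]]
  }
  hi <- if (x == n) 1 else {
    lower_tail <- stats::pbinom(x, n, grid)
    ok <- which(lower_tail >= alpha / 2)
    grid[ok[length(ok)]]
  }
  c(lower = lo, upper = hi)
}

## Small benchmark phantom spec (coarse geometry keeps tests quick).
tiny_phantom_spec <- function(..., depth_mm = 0.88) {
  phantom_spec(field_mm = c(3, 3), depth_mm = depth_mm,
               voxel_um = c(dz = 8, dy = 24, dx = 24), ...)
}
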