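# Simulation engine: initialization, the per-step update loop, dosing,
# replicate execution and time-series recording.
#
# Agent state lives in parallel vectors (struct-of-arrays); every phase
# of a step is vectorized over the agents it touches. Where simultaneous
# actions can conflict (two NK agents killing the same tumor cell, two
# daughters placed into a cell with one free slot) conflicts are
# resolved by uniformly random priority, which reproduces the statistics
# of a randomly ordered sequential sweep without its cost.

PHEN_NC <- 1L; PHEN_NE <- 2L; PHEN_NV <- 3L

lin_index <- function(cfg, row, col) (col - 1L) * cfg$height + row

empty_nk <- function(n_markers = 0L) {
  list(row = integer(), col = integer(), phen = integer(),
       c_nk = numeric(), kills = numeric(), s = numeric(),
       age = integer(), exposed = logical(), product = integer(),
       static = numeric(),
       markers = matrix(0, 0, n_markers))
}

empty_tumor <- function() {
  list(row = integer(), col = integer(), antigen = numeric(),
       mutations = integer())
}

nk_count <- function(nk) length(nk$row)
tumor_count_total <- function(tumor) length(tumor$row)

subset_nk <- function(nk, keep) {
  list(row = nk$row[keep], col = nk$col[keep], phen = nk$phen[keep],
       c_nk = nk$c_nk[keep], kills = nk$kills[keep], s = nk$s[keep],
       age = nk$age[keep], exposed = nk$exposed[keep],
       product = nk$product[keep], static = nk$static[keep],
       markers = nk$markers[keep, , drop = FALSE])
}

bind_nk <- function(a, b) {
  list(row = c(a$row, b$row), col = c(a$col, b$col),
       phen = c(a$phen, b$phen), c_nk = c(a$c_nk, b$c_nk),
       kills = c(a$kills, b$kills), s = c(a$s, b$s),
       age = c(a$age, b$age), exposed = c(a$exposed, b$exposed),
       product = c(a$product, b$product), static = c(a$static, b$static),
       markers = rbind(a$markers, b$markers))
}

subset_tumor <- function(tumor, keep) {
  list(row = tumor$row[keep], col = tumor$col[keep],
       antigen = tumor$antigen[keep], mutations = tumor$mutations[keep])
}

bind_tumor <- function(a, b) {
  list(row = c(a$row, b$row), col = c(a$col, b$col),
       antigen = c(a$antigen, b$antigen),
       mutations = c(a$mutations, b$mutations))
}

refresh_tumor_count <- function(model) {
  cfg <- model$cfg$grid
  lin <- lin_index(cfg, model$tumor$row, model$tumor$col)
  model$grid$tumor_count <- matrix(
    tabulate(lin, nbins = cfg$height * cfg$width), cfg$height, cfg$width)
  model
}

# ---------------------------------------------------------------------
# Initialization

# Fill cells in a given order up to capacity until n agents are placed.
pack_cells <- function(order_lin, cap, n, cfg) {
  full <- rep(cap, length(order_lin))
  cum <- cumsum(full)
  k <- which(cum >= n)[1]
  if (is.na(k)) stop("grid too small for ", n, " tumor cells")
  counts <- full[seq_len(k)]
  counts[k] <- counts[k] - (cum[k] - n)
  cells <- rep(order_lin[seq_len(k)], counts)
  row <- ((cells - 1L) %% cfg$height) + 1L
  col <- ((cells - 1L) %/% cfg$height) + 1L
  list(row = row, col = col)
}

place_tumor_disk <- function(cfg, n) {
  cr <- (cfg$height + 1) / 2; cc <- (cfg$width + 1) / 2
  rows <- rep(seq_len(cfg$height), cfg$width)
  cols <- rep(seq_len(cfg$width), each = cfg$height)
  d2 <- (rows - cr)^2 + (cols - cc)^2
  ord <- order(d2, stats::runif(length(d2)))
  pack_cells(lin_index(cfg, rows, cols)[ord], cfg$b_max, n, cfg)
}

place_tumor_uniform <- function(cfg, n, existing_counts = NULL) {
  ncell <- cfg$height * cfg$width
  counts <- if (is.null(existing_counts)) integer(ncell)
            else as.integer(existing_counts)
  if (sum(cfg$b_max - counts) < n) stop("grid too small for ", n, " tumor cells")
  placed <- integer(0)
  need <- n
  while (need > 0) {
    cand <- sample.int(ncell, need, replace = TRUE)
    add <- tabulate(cand, nbins = ncell)
    newc <- counts + add
    over <- pmax(newc - cfg$b_max, 0L)
    # reject the overflow draws per cell, keep the rest
    if (any(over > 0)) {
      keep <- integer(0)
      ok_cells <- add > 0 & over == 0
      keep <- cand[cand %in% which(ok_cells)]
      for (cell in which(add > 0 & over > 0)) {
        take <- add[cell] - over[cell]
        if (take > 0) keep <- c(keep, rep(cell, take))
      }
      cand <- keep
    }
    counts <- counts + tabulate(cand, nbins = ncell)
    placed <- c(placed, cand)
    need <- n - length(placed)
  }
  row <- ((placed - 1L) %% cfg$height) + 1L
  col <- ((placed - 1L) %/% cfg$height) + 1L
  list(row = row, col = col)
}

place_nk_positions <- function(cfg, n, mode, tumor_radius = 0) {
  rows <- rep(seq_len(cfg$height), cfg$width)
  cols <- rep(seq_len(cfg$width), each = cfg$height)
  if (mode == "periphery") {
    border_dist <- pmin(rows - 1L, cfg$height - rows,
                        cols - 1L, cfg$width - cols)
    cand <- which(border_dist <= 2L)
  } else { # adjacent: annulus just outside the tumor mass
    cr <- (cfg$height + 1) / 2; cc <- (cfg$width + 1) / 2
    d <- sqrt((rows - cr)^2 + (cols - cc)^2)
    cand <- which(d > tumor_radius & d <= tumor_radius + 3)
    if (!length(cand)) cand <- seq_along(rows)
  }
  pick <- cand[sample.int(length(cand), n, replace = TRUE)]
  list(row = rows[pick], col = cols[pick])
}

# Build a cohort of freshly infused cytotoxic NK agents of one product.
make_nk_cohort <- function(model, product_name, n, positions) {
  cfg <- model$cfg
  pidx <- match(product_name, names(cfg$products))
  if (is.na(pidx)) stop("unknown NK product: ", product_name)
  prod <- cfg$products[[pidx]]
  c_nk <- sample_baseline_cytotoxicity(prod$kill, n)
  if (!is.null(cfg$effect_table) && !is.null(cfg$expression_pool)) {
    idx <- assign_expression_profiles(cfg$expression_pool, n)
    gen <- precompute_genetics(cfg$effect_table, cfg$expression_pool, idx)
  } else {
    gen <- list(static = rep(0, n),
                markers = matrix(0, n, model$n_markers),
                marker_beta = model$marker_beta)
  }
  if (ncol(gen$markers) != model$n_markers)
    stop("marker dimension mismatch in NK cohort")
  list(row = positions$row, col = positions$col,
       phen = rep(PHEN_NC, n), c_nk = c_nk,
       kills = rep(0, n), s = rep(as.numeric(prod$exhaustion$s0), n),
       age = rep(0L, n), exposed = rep(FALSE, n),
       product = rep(pidx, n), static = gen$static,
       markers = gen$markers)
}

#' Initialize a simulation state
#'
#' Packs `n_tumor_init` tumor cells into the configured placement
#' geometry, infuses `n_nk_init` cytotoxic NK agents of the initial
#' product, assigns expression profiles, and allocates the cytokine
#' fields. Call with the RNG already seeded (or use [run_simulation()]).
#'
#' @param config A [simulation_config()].
#' @return A model state list (grid, agent vectors, counters).
#' @export
initialize_tme <- function(config) {
  cfg <- config$grid
  table <- config$effect_table
  marker_beta <- if (!is.null(table)) table$beta[table$is_exhaustion_marker]
                 else numeric(0)
  model <- list(cfg = config,
                grid = tme_grid(cfg, config$cytokines),
                step_idx = 0L,
                n_markers = length(marker_beta),
                marker_beta = marker_beta,
                tumor = empty_tumor(),
                nk = empty_nk(length(marker_beta)),
                cum = list(deaths_cyto = 0, deaths_prog = 0,
                           divisions = 0, mutated = 0),
                last_pc_mean = NA_real_,
                dosed = logical(nrow(config$dosing)),
                rechallenged = logical(length(config$rechallenge_days)),
                record = list())

  n_b <- config$n_tumor_init
  tumor_radius <- 0
  if (n_b > 0) {
    pos <- switch(config$tumor_placement,
                  disk = place_tumor_disk(cfg, n_b),
                  uniform = place_tumor_uniform(cfg, n_b))
    antigen <- if (!is.null(config$antigen_pool))
      config$antigen_pool[sample.int(length(config$antigen_pool), n_b,
                                     replace = TRUE)]
    else rep(1, n_b)
    model$tumor <- list(row = pos$row, col = pos$col, antigen = antigen,
                        mutations = rep(0L, n_b))
    cr <- (cfg$height + 1) / 2; cc <- (cfg$width + 1) / 2
    tumor_radius <- max(sqrt((pos$row - cr)^2 + (pos$col - cc)^2))
  }
  model <- refresh_tumor_count(model)

  n_nk <- config$n_nk_init
  if (config$assay_mode == "autonomous_growth" && n_b > 0)
    stop("autonomous_growth mode is tumor-free; set n_tumor_init = 0")
  if (n_nk > 0) {
    pos <- place_nk_positions(cfg, n_nk, config$nk_placement, tumor_radius)
    model$nk <- make_nk_cohort(model, config$initial_product, n_nk, pos)
  }
  model$n_tumor0 <- max(n_b, 1L)
  model$n_nk0 <- max(n_nk, 1L)
  model$tumor_radius <- tumor_radius
  model <- record_metrics(model)
  model
}

# ---------------------------------------------------------------------
# Phases

# Stochastic rounding: expectation equals x.
stoch_round <- function(x, n) {
  base <- floor(x)
  base + (stats::runif(n) < (x - base))
}

OFF_R <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
OFF_C <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)

# One chemotactic/random sub-step for the selected NK agents.
nk_substep <- function(model, who) {
  cfg <- model$cfg$grid
  n <- length(who)
  if (!n) return(model)
  row <- model$nk$row[who]; col <- model$nk$col[who]
  cand_r <- outer(row, OFF_R, `+`)
  cand_c <- outer(col, OFF_C, `+`)
  valid <- cand_r >= 1L & cand_r <= cfg$height &
    cand_c >= 1L & cand_c <= cfg$width
  key <- matrix(-Inf, n, 8L)
  any_tumor <- tumor_count_total(model$tumor) > 0
  if (any_tumor) {
    # primary: local tumor load of the candidate cell; secondary: distance
    # to the tumor centroid (carries the gradient across empty regions)
    load <- nbhd_sum(model$grid$tumor_count, 1L)
    cr <- mean(model$tumor$row); cc <- mean(model$tumor$col)
    idx <- cbind(as.vector(cand_r), as.vector(cand_c))
    idx[!valid, ] <- 1L
    v <- matrix(load[idx], n, 8L)
    d2 <- (cand_r - cr)^2 + (cand_c - cc)^2
    key <- v * 1e8 - d2 + matrix(stats::runif(n * 8L, 0, 0.49), n, 8L)
  } else {
    key <- matrix(stats::runif(n * 8L), n, 8L)
  }
  key[!valid] <- -Inf
  pick <- max.col(key, ties.method = "first")
  sel <- cbind(seq_len(n), pick)
  model$nk$row[who] <- cand_r[sel]
  model$nk$col[who] <- cand_c[sel]
  model
}

phase_nk_move <- function(model) {
  nk <- model$nk
  n <- nk_count(nk)
  if (!n) return(model)
  cfgs <- model$cfg
  m_n <- vapply(cfgs$products, function(p) p$motility$m_n, 0)
  v_n <- vapply(cfgs$products, function(p) p$motility$v_n, 0)
  dt <- cfgs$grid$dt; l <- cfgs$grid$l
  mover <- stats::runif(n) < m_n[nk$product]
  if (!any(mover)) return(model)
  steps_mean <- v_n[nk$product] * dt / l
  nsub <- ifelse(mover, stoch_round(steps_mean, n), 0L)
  for (k in seq_len(max(nsub))) {
    who <- which(nsub >= k)
    model <- nk_substep(model, who)
  }
  model
}

phase_nk_kill <- function(model) {
  nk <- model$nk
  cfg <- model$cfg$grid
  n <- nk_count(nk)
  nt <- tumor_count_total(model$tumor)
  if (!n || !nt) return(model)
  is_nc <- nk$phen == PHEN_NC
  if (!any(is_nc)) return(model)
  nc <- which(is_nc)
  row <- nk$row[nc]; col <- nk$col[nc]
  m <- length(nc)
  cand_r <- cbind(row, outer(row, OFF_R, `+`))
  cand_c <- cbind(col, outer(col, OFF_C, `+`))
  valid <- cand_r >= 1L & cand_r <= cfg$height &
    cand_c >= 1L & cand_c <= cfg$width
  idx <- cbind(as.vector(cand_r), as.vector(cand_c))
  idx[!valid, ] <- 1L
  counts <- matrix(model$grid$tumor_count[idx], m, 9L)
  counts[!valid] <- 0L
  total <- rowSums(counts)
  # any tumor contact marks exposure
  model$nk$exposed[nc[total > 0]] <- TRUE
  can <- total > 0 & nk$s[nc] > 0
  if (!any(can)) return(model)
  att <- which(can)
  # choose one of the 9 cells weighted by its tumor count
  cum <- counts[att, , drop = FALSE]
  for (j in 2:9) cum[, j] <- cum[, j] + cum[, j - 1]
  u <- stats::runif(length(att)) * total[att]
  cell_pick <- max.col(cum >= u, ties.method = "first")
  sel <- cbind(seq_along(att), cell_pick)
  tr <- cand_r[att, , drop = FALSE][sel]
  tc <- cand_c[att, , drop = FALSE][sel]
  # map (cell, uniform index) to a concrete tumor agent
  tlin <- lin_index(cfg, model$tumor$row, model$tumor$col)
  ord <- order(tlin)
  sorted <- tlin[ord]
  cell_lin <- lin_index(cfg, tr, tc)
  first <- findInterval(cell_lin - 0.5, sorted) + 1L
  ccount <- model$grid$tumor_count[cbind(tr, tc)]
  j <- floor(stats::runif(length(att)) * ccount)
  target <- ord[first + j]

  agents <- nc[att]
  prods <- model$cfg$products
  b_vec <- vapply(prods, function(p) p$genetics$b, 0)[nk$product[agents]]
  gamma_vec <- vapply(prods, function(p) p$kill$gamma, 0)[nk$product[agents]]
  g_nk <- genetic_effect_vec(b_vec, nk$static[agents],
                             nk$markers[agents, , drop = FALSE],
                             model$marker_beta)
  p_ev <- effective_evasion(model$cfg$tumor,
                            model$tumor$antigen[target],
                            model$tumor$mutations[target])
  pk <- compute_pkill(nk$c_nk[agents], g_nk, gamma_vec, p_ev)
  success <- stats::runif(length(att)) < pk
  if (!any(success)) return(model)
  sidx <- which(success)
  # random priority among agents claiming the same target
  perm <- sample(sidx)
  win <- perm[!duplicated(target[perm])]
  killed <- target[win]
  killers <- agents[win]

  model$cum$deaths_cyto <- model$cum$deaths_cyto + length(killed)
  model$nk$kills[killers] <- model$nk$kills[killers] + 1
  variant <- vapply(prods, function(p) p$exhaustion$variant, "")
  upd_markers <- variant[model$nk$product[killers]] %in% c("EM2", "EM3")
  if (model$n_markers && any(upd_markers)) {
    km <- killers[upd_markers]
    model$nk$markers[km, ] <- model$nk$markers[km, , drop = FALSE] + 1
  }
  # recompute remaining capacity per product variant
  for (pi in unique(model$nk$product[killers])) {
    kk <- killers[model$nk$product[killers] == pi]
    model$nk$s[kk] <- skc_remaining(prods[[pi]]$exhaustion,
                                    model$nk$kills[kk],
                                    model$nk$markers[kk, , drop = FALSE])
  }
  keep <- rep(TRUE, nt); keep[killed] <- FALSE
  model$tumor <- subset_tumor(model$tumor, keep)
  refresh_tumor_count(model)
}

phase_tumor <- function(model) {
  tp <- model$cfg$tumor
  cfg <- model$cfg$grid
  dt_days <- cfg$dt / 24
  nt <- tumor_count_total(model$tumor)
  if (!nt) return(model)
  # programmed death
  die <- stats::runif(nt) < p_step_death(tp$d_b, dt_days)
  if (any(die)) {
    model$cum$deaths_prog <- model$cum$deaths_prog + sum(die)
    model$tumor <- subset_tumor(model$tumor, !die)
    model <- refresh_tumor_count(model)
    nt <- tumor_count_total(model$tumor)
    if (!nt) return(model)
  }
  # division with carrying-capacity placement
  divide <- which(stats::runif(nt) < p_step_division(tp$p_b, dt_days))
  if (length(divide)) {
    model <- place_daughters(model, divide)
  }
  # movement
  model <- phase_tumor_move(model)
  model
}

# Place daughters of dividing tumor cells: in the mother's cell while it
# has spare capacity, else into a uniformly random non-full Moore-1
# neighbor, else the division is skipped. Simultaneous placements are
# admitted in uniformly random priority so the per-cell cap is never
# exceeded.
place_daughters <- function(model, divide) {
  cfg <- model$cfg$grid
  tp <- model$cfg$tumor
  ncell <- cfg$height * cfg$width
  counts <- as.integer(model$grid$tumor_count)
  mlin <- lin_index(cfg, model$tumor$row[divide], model$tumor$col[divide])
  # in-cell admissions, random priority within each cell
  perm <- sample(seq_along(divide))
  ranked <- stats::ave(seq_along(perm), mlin[perm], FUN = seq_along)
  free <- cfg$b_max - counts
  in_cell <- ranked <= free[mlin[perm]]
  placed_lin <- mlin[perm][in_cell]
  mothers <- divide[perm][in_cell]
  counts <- counts + tabulate(placed_lin, nbins = ncell)
  # overflow dividers try a random non-full neighbor
  over <- divide[perm][!in_cell]
  if (length(over)) {
    free_mat <- matrix(pmax(cfg$b_max - counts, 0L), cfg$height, cfg$width)
    # cheap pre-filter: skip dividers whose whole neighborhood is full
    nb_free <- nbhd_sum(free_mat, 1L) - free_mat  # free slots among neighbors
    olin <- lin_index(cfg, model$tumor$row[over], model$tumor$col[over])
    over <- over[nb_free[olin] > 0]
    for (i in over) {
      r <- model$tumor$row[i]; c <- model$tumor$col[i]
      nr <- r + OFF_R; nc <- c + OFF_C
      ok <- nr >= 1L & nr <= cfg$height & nc >= 1L & nc <= cfg$width
      nl <- lin_index(cfg, nr[ok], nc[ok])
      open <- nl[counts[nl] < cfg$b_max]
      if (length(open)) {
        pick <- open[sample.int(length(open), 1L)]
        counts[pick] <- counts[pick] + 1L
        placed_lin <- c(placed_lin, pick)
        mothers <- c(mothers, i)
      }
    }
  }
  nd <- length(mothers)
  if (nd) {
    drow <- ((placed_lin - 1L) %% cfg$height) + 1L
    dcol <- ((placed_lin - 1L) %/% cfg$height) + 1L
    mut_gain <- stats::runif(nd) < tp$p_mutate
    daughters <- list(row = drow, col = dcol,
                      antigen = model$tumor$antigen[mothers],
                      mutations = model$tumor$mutations[mothers] +
                        as.integer(mut_gain))
    model$cum$divisions <- model$cum$divisions + nd
    model$cum$mutated <- model$cum$mutated + sum(mut_gain)
    model$tumor <- bind_tumor(model$tumor, daughters)
    model <- refresh_tumor_count(model)
  }
  model
}

phase_tumor_move <- function(model) {
  tp <- model$cfg$tumor
  cfg <- model$cfg$grid
  nt <- tumor_count_total(model$tumor)
  if (!nt || tp$m_b <= 0 || tp$v_b < 1L) return(model)
  for (sub in seq_len(tp$v_b)) {
    mover <- which(stats::runif(nt) < tp$m_b)
    if (!length(mover)) next
    dirs <- sample.int(8L, length(mover), replace = TRUE)
    pr <- pmin(pmax(model$tumor$row[mover] + OFF_R[dirs], 1L), cfg$height)
    pc <- pmin(pmax(model$tumor$col[mover] + OFF_C[dirs], 1L), cfg$width)
    ncell <- cfg$height * cfg$width
    from <- lin_index(cfg, model$tumor$row[mover], model$tumor$col[mover])
    to <- lin_index(cfg, pr, pc)
    moving <- from != to
    mover <- mover[moving]; from <- from[moving]; to <- to[moving]
    if (!length(mover)) next
    counts <- as.integer(model$grid$tumor_count)
    counts <- counts - tabulate(from, nbins = ncell) +
      tabulate(to, nbins = ncell)
    # bounce back random excess arrivals until every cell respects b_max
    active <- rep(TRUE, length(mover))
    while (TRUE) {
      bad <- which(counts > cfg$b_max)
      if (!length(bad)) break
      rej_all <- integer(0)
      for (cell in bad) {
        arr <- which(active & to == cell)
        nrej <- min(counts[cell] - cfg$b_max, length(arr))
        rej <- arr[sample.int(length(arr), nrej)]
        active[rej] <- FALSE
        counts[cell] <- counts[cell] - nrej
        rej_all <- c(rej_all, rej)
      }
      if (!length(rej_all)) break
      counts <- counts + tabulate(from[rej_all], nbins = ncell)
    }
    ok <- which(active)
    model$tumor$row[mover[ok]] <- ((to[ok] - 1L) %% cfg$height) + 1L
    model$tumor$col[mover[ok]] <- ((to[ok] - 1L) %/% cfg$height) + 1L
    model <- refresh_tumor_count(model)
  }
  model
}

phase_nk_transitions <- function(model) {
  nk <- model$nk
  n <- nk_count(nk)
  if (!n) return(model)
  prods <- model$cfg$products
  rates_kbm <- vapply(prods, function(p) p$rates$kb_minus, 0)
  rates_kbp <- vapply(prods, function(p) p$rates$kb_plus, 0)
  s0s <- vapply(prods, function(p) as.numeric(p$exhaustion$s0), 0)
  # exhaustion: depleted cytotoxic agents become exhausted
  dep <- nk$phen == PHEN_NC & nk$s <= 0
  model$nk$phen[dep] <- PHEN_NE
  # local tumor presence within Moore-1 at end-of-step occupancy
  load <- nbhd_sum(model$grid$tumor_count, 1L)
  local_b <- load[cbind(nk$row, nk$col)]
  # cytotoxic -> vigilant on local clearance after exposure
  elig <- model$nk$phen == PHEN_NC & nk$exposed & local_b == 0
  if (any(elig)) {
    go <- elig & stats::runif(n) < rates_kbm[nk$product]
    model$nk$phen[go] <- PHEN_NV
  }
  # vigilant -> cytotoxic recall on tumor re-exposure; capacity restored
  stim <- model$nk$phen == PHEN_NV & local_b > 0
  if (any(stim)) {
    back <- stim & stats::runif(n) < rates_kbp[nk$product]
    if (any(back)) {
      model$nk$phen[back] <- PHEN_NC
      model$nk$s[back] <- s0s[nk$product[back]]
      model$nk$kills[back] <- 0
    }
  }
  model
}

phase_nk_demography <- function(model) {
  nk <- model$nk
  n <- nk_count(nk)
  model$last_pc_mean <- NA_real_
  if (!n) return(model)
  cfgs <- model$cfg
  dt_days <- cfgs$grid$dt / 24
  prods <- cfgs$products
  autonomous <- cfgs$assay_mode == "autonomous_growth"

  death_rate <- numeric(n)
  for (pi in seq_along(prods)) {
    sel <- nk$product == pi
    r <- prods[[pi]]$rates
    death_rate[sel & nk$phen == PHEN_NC] <- r$d_c
    death_rate[sel & nk$phen == PHEN_NE] <- r$d_e
    death_rate[sel & nk$phen == PHEN_NV] <- r$d_v
  }
  die <- stats::runif(n) < p_step_death(death_rate, dt_days)

  # division: cytotoxic agents follow the stimulus model, vigilant and
  # exhausted divide at their constant phenotype rates
  div_p <- numeric(n)
  ctot <- total_cytokine(model$grid)
  load <- nbhd_sum(model$grid$tumor_count, 1L)
  pc_samples <- numeric(0)
  for (pi in seq_along(prods)) {
    pr <- prods[[pi]]
    sel_nc <- which(nk$product == pi & nk$phen == PHEN_NC)
    if (length(sel_nc)) {
      b_local <- load[cbind(nk$row[sel_nc], nk$col[sel_nc])]
      c_local <- ctot[cbind(nk$row[sel_nc], nk$col[sel_nc])]
      st <- stimulus_terms(pr$prolif, b_local, c_local, autonomous)
      rate <- proliferation_rate(pr$prolif, nk$age[sel_nc], st$w)
      pc_samples <- c(pc_samples, rate)
      div_p[sel_nc] <- p_step_division(rate, dt_days)
    }
    sel <- nk$product == pi
    div_p[sel & nk$phen == PHEN_NV] <-
      p_step_division(pr$rates$p_v, dt_days)
    div_p[sel & nk$phen == PHEN_NE] <-
      p_step_division(pr$rates$p_e, dt_days)
  }
  model$last_pc_mean <- if (length(pc_samples)) mean(pc_samples) else NA_real_
  divide <- stats::runif(n) < div_p
  if (any(divide)) {
    mom <- which(divide)
    daughters <- subset_nk(nk, mom)
    daughters$age <- rep(0L, length(mom))
    model$nk <- bind_nk(model$nk, daughters)
    die <- c(die, rep(FALSE, length(mom)))
  }
  if (any(die)) model$nk <- subset_nk(model$nk, !die)
  model$nk$age <- model$nk$age + 1L
  model
}

phase_cytokine <- function(model) {
  if (!length(model$grid$cytokine)) return(model)
  nk <- model$nk
  armored <- list()
  sp_by_prod <- vapply(model$cfg$products, function(p)
    if (is.na(p$armored)) "" else p$armored, "")
  for (sp in names(model$grid$cytokine)) {
    prods_sp <- which(sp_by_prod == sp)
    sel <- nk$product %in% prods_sp
    armored[[sp]] <- cbind(nk$row[sel], nk$col[sel])
  }
  model$grid <- update_cytokine_field(model$grid, armored)
  model
}

#' Infuse a follow-up NK dose
#'
#' Adds `multiplier * n_tumor_init * etr` freshly sampled cytotoxic NK
#' agents of the named product at the configured NK placement.
#'
#' @param model A model state.
#' @param product Product name (must exist in the config).
#' @param multiplier Dose multiplier relative to 1X.
#' @return The updated model.
#' @export
apply_dose <- function(model, product, multiplier = 1) {
  cfgs <- model$cfg
  n <- as.integer(round(multiplier * cfgs$n_tumor_init * cfgs$etr))
  if (n <= 0L) return(model)
  pos <- place_nk_positions(cfgs$grid, n, cfgs$nk_placement,
                            model$tumor_radius)
  model$nk <- bind_nk(model$nk, make_nk_cohort(model, product, n, pos))
  model
}

phase_dosing <- function(model) {
  cfgs <- model$cfg
  day <- model$step_idx * cfgs$grid$dt / 24
  due <- which(!model$dosed & cfgs$dosing$day <= day)
  for (i in due) {
    model <- apply_dose(model, cfgs$dosing$product[i],
                        cfgs$dosing$multiplier[i])
    model$dosed[i] <- TRUE
  }
  if (cfgs$assay_mode == "rechallenge") {
    dueb <- which(!model$rechallenged & cfgs$rechallenge_days <= day)
    for (i in dueb) {
      pos <- place_tumor_uniform(cfgs$grid, cfgs$rechallenge_size,
                                 model$grid$tumor_count)
      bolus <- list(row = pos$row, col = pos$col,
                    antigen = rep(1, length(pos$row)),
                    mutations = rep(0L, length(pos$row)))
      model$tumor <- bind_tumor(model$tumor, bolus)
      model <- refresh_tumor_count(model)
      model$rechallenged[i] <- TRUE
    }
  }
  model
}

record_metrics <- function(model) {
  cfgs <- model$cfg
  nk <- model$nk
  b <- tumor_count_total(model$tumor)
  n_nc <- sum(nk$phen == PHEN_NC)
  n_ne <- sum(nk$phen == PHEN_NE)
  n_nv <- sum(nk$phen == PHEN_NV)
  inter <- 0
  if (b > 0 && n_nc > 0) {
    cfg <- cfgs$grid
    nc_cells <- unique(lin_index(cfg, nk$row[nk$phen == PHEN_NC],
                                 nk$col[nk$phen == PHEN_NC]))
    tl <- lin_index(cfg, model$tumor$row, model$tumor$col)
    inter <- mean(tl %in% nc_cells)
  }
  ctot <- total_cytokine(model$grid)
  row <- data.frame(step = model$step_idx,
                    day = model$step_idx * cfgs$grid$dt / 24,
                    B = b, NC = n_nc, NE = n_ne, NV = n_nv,
                    deaths_cytotoxic_cum = model$cum$deaths_cyto,
                    deaths_programmed_cum = model$cum$deaths_prog,
                    divisions_cum = model$cum$divisions,
                    mutated_cum = model$cum$mutated,
                    cytokine_mean = mean(ctot),
                    pc_mean = model$last_pc_mean,
                    interaction_rate = inter,
                    fold_B = b / model$n_tumor0,
                    fold_NK = (n_nc + n_ne + n_nv) / model$n_nk0,
                    max_tumor_per_cell = max(model$grid$tumor_count))
  model$record[[length(model$record) + 1L]] <- row
  model
}

#' Advance the simulation by one step
#'
#' One tick of length `dt`: NK movement, NK kill attempts, tumor
#' division/death/movement, NK phenotype transitions and demography,
#' cytokine decay and deposition, dosing events, metric recording.
#'
#' @param model A model state from [initialize_tme()].
#' @return The advanced model.
#' @export
step_model <- function(model) {
  model$step_idx <- model$step_idx + 1L
  model <- phase_nk_move(model)
  model <- phase_nk_kill(model)
  model <- phase_tumor(model)
  model <- phase_nk_transitions(model)
  model <- phase_nk_demography(model)
  model <- phase_cytokine(model)
  model <- phase_dosing(model)
  if (model$step_idx %% model$cfg$record_every == 0L)
    model <- record_metrics(model)
  model
}

record_df <- function(model) do.call(rbind, model$record)

#' Run one replicate
#'
#' Seeds the RNG, initializes the state and advances it for the
#' configured duration.
#'
#' @param config A [simulation_config()].
#' @param seed Seed for this replicate (default the config's base seed).
#' @return `list(record = data.frame, model = final state)`.
#' @export
run_simulation <- function(config, seed = config$seed) {
  set.seed(seed)
  model <- initialize_tme(config)
  n_steps <- ceiling(config$duration * 24 / config$grid$dt)
  for (k in seq_len(n_steps)) model <- step_model(model)
  list(record = record_df(model), model = model)
}

#' Run replicates and aggregate
#'
#' Replicate `r` uses seed `config$seed + r - 1`. Aggregation is
#' pointwise over recorded steps.
#'
#' @param config A [simulation_config()].
#' @param replicates Number of replicates (default from the config).
#' @return `list(replicates = list of records, mean = data.frame,
#'   sd = data.frame)`.
#' @export
run_replicates <- function(config, replicates = config$replicates) {
  recs <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    recs[[r]] <- run_simulation(config, seed = config$seed + r - 1L)$record
  }
  num_cols <- names(recs[[1]])
  arr <- simplify2array(lapply(recs, function(d) as.matrix(d[num_cols])))
  mu <- apply(arr, c(1, 2), mean)
  sdv <- if (replicates > 1) apply(arr, c(1, 2), stats::sd) else mu * 0
  list(replicates = recs,
       mean = as.data.frame(mu),
       sd = as.data.frame(sdv))
}

#' Run a matched tumor-only control
#'
#' Same configuration and seeds with all NK removed; used to normalize
#' treated tumor burden the way in vivo radiance is normalized by the
#' tumor-only control group.
#'
#' @param config A [simulation_config()].
#' @param replicates Number of replicates.
#' @return As [run_replicates()].
#' @export
run_control <- function(config, replicates = config$replicates) {
  ctrl <- config
  ctrl$n_nk_init <- 0L
  ctrl$dosing <- dosing_schedule()
  run_replicates(ctrl, replicates)
}

#' Write a time-series record to CSV
#'
#' @param record Data frame from [run_simulation()] or an aggregate.
#' @param path Output path.
#' @export
write_record_csv <- function(record, path) {
  utils::write.csv(record, path, row.names = FALSE)
}
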