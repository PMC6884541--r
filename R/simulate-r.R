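# Reference engine: the annual loop composed from the package's R-level
# operations (hydrology runs through the same compiled weekly kernel).  It
# mirrors run_simulation(engine = "cpp") record for record and exists so the
# compiled loop can be audited against its parts on small configurations.

simulate_transect_r <- function(params, climate, n_cols, dx, lagg_head,
                                ditch_cols, ditch_depth, open_year,
                                budget_from_year, hydro_substeps, n_years,
                                pin_surface) {
  cols <- lapply(seq_len(n_cols), function(i) {
    peat_column(x_position = (i - 0.5) * dx, width = dx)
  })
  cols[[n_cols]]$fixed <- TRUE
  cols[[n_cols]]$fixed_head <- lagg_head
  cols[[n_cols]]$head <- lagg_head
  grows <- c(rep(TRUE, n_cols - 1), FALSE)
  grp <- replicate(n_cols, integer(), simplify = FALSE)

  mats <- c("total_mass", "height", "mean_wtd", "litter", "oxic_loss",
            "anoxic_loss", "runoff", "excavated")
  yearly <- stats::setNames(
    lapply(mats, function(v) matrix(0, n_years, n_cols)), mats)

  cum_litter <- cum_decay <- cum_excav <- numeric(n_cols)
  budget <- budget_from_year > 0
  bud <- list(stock0 = numeric(n_cols), lossA = numeric(n_cols),
              lossC = numeric(n_cols), lossN = numeric(n_cols),
              excav = numeric(n_cols))

  for (y in seq_len(n_years)) {
    if (open_year > 0 && y == open_year) {
      for (i in ditch_cols) {
        ex <- excavate_ditch(cols[[i]], ditch_depth, params)
        # keep the group labels aligned with the surviving records
        grp[[i]] <- grp[[i]][seq_along(ex$column$mass)]
        cols[[i]] <- ex$column
        grows[i] <- FALSE
        cum_excav[i] <- cum_excav[i] + ex$removed_mass
        yearly$excavated[y, i] <- ex$removed_mass
        if (budget && y > budget_from_year) bud$excav[i] <- bud$excav[i] + ex$removed_mass
      }
    }

    tran <- make_transect(cols, dx)
    surf0 <- vapply(cols, function(cl) cl$base + sum(cl$mass) / params$bulk_density, 0)
    f_acc <- lapply(cols, function(cl) numeric(length(cl$mass)))
    head_sum <- wtd_sum <- runoff_y <- numeric(n_cols)

    for (w in seq_len(52)) {
      r_cm <- climate$rain_cm[y, w]
      if (pin_surface) {
        for (i in seq_len(n_cols)) {
          if (!tran$columns[[i]]$fixed) {
            tran$columns[[i]]$head <- surf0[i]
            runoff_y[i] <- runoff_y[i] + max(r_cm / 100, 0)
          }
        }
      } else {
        hs <- hydro_step(tran, r_cm, params, hydro_substeps,
                         week = (y - 1L) * 52L + w)
        tran <- hs$transect
        runoff_y <- runoff_y + hs$runoff_depth
      }
      for (i in seq_len(n_cols)) {
        h <- tran$columns[[i]]$head
        head_sum[i] <- head_sum[i] + h
        wtd_sum[i] <- wtd_sum[i] + max(0, surf0[i] - h)
        if (length(f_acc[[i]])) {
          f_acc[[i]] <- f_acc[[i]] +
            oxic_fractions(tran$columns[[i]], params, h)
        }
      }
    }
    cols <- tran$columns
    tfac_year <- climate$temperature_C[y]

    for (i in seq_len(n_cols)) {
      mean_wtd <- wtd_sum[i] / 52
      f <- if (length(f_acc[[i]])) f_acc[[i]] / 52 else numeric()

      dec <- decompose_cohorts(cols[[i]], f, tfac_year, 1, params)
      if (budget && y > budget_from_year && length(grp[[i]])) {
        loss_j <- cols[[i]]$mass - dec$column$mass
        bud$lossA[i] <- bud$lossA[i] + sum(loss_j[grp[[i]] == 1])
        bud$lossC[i] <- bud$lossC[i] + sum(loss_j[grp[[i]] == 2])
        bud$lossN[i] <- bud$lossN[i] + sum(loss_j[grp[[i]] == 0])
      }
      cols[[i]] <- dec$column
      cum_decay[i] <- cum_decay[i] + dec$oxic_loss + dec$anoxic_loss
      yearly$oxic_loss[y, i] <- dec$oxic_loss
      yearly$anoxic_loss[y, i] <- dec$anoxic_loss

      p <- 0
      if (grows[i]) {
        p <- litter_production(mean_wtd, climate$temperature_C[y], params)
        if (p > 0) {
          cols[[i]] <- add_annual_cohort(cols[[i]], p, y)
          grp[[i]] <- c(grp[[i]],
                        if (budget && y > budget_from_year) 0L else -1L)
          cum_litter[i] <- cum_litter[i] + p
        }
      }
      yearly$litter[y, i] <- p

      agg <- aggregate_with_groups(cols[[i]], grp[[i]], params,
                                   water_table = cols[[i]]$head)
      cols[[i]] <- agg$column
      grp[[i]] <- agg$group

      yearly$total_mass[y, i] <- sum(cols[[i]]$mass)
      yearly$height[y, i] <- sum(cols[[i]]$mass) / params$bulk_density
      yearly$mean_wtd[y, i] <- mean_wtd
      yearly$runoff[y, i] <- runoff_y[i]

      if (budget && y == budget_from_year) {
        bud$stock0[i] <- sum(cols[[i]]$mass)
        wt_elev <- head_sum[i] / 52
        th <- cols[[i]]$mass / params$bulk_density
        zmid <- cols[[i]]$base + cumsum(th) - th / 2
        grp[[i]] <- ifelse(zmid > wt_elev, 1L, 2L)
      }
    }
  }

  final <- lapply(seq_len(n_cols), function(i) {
    list(mass = cols[[i]]$mass, initial_mass = cols[[i]]$initial_mass,
         year_young = cols[[i]]$year_young, year_old = cols[[i]]$year_old,
         year_mean = cols[[i]]$year_mean, group = grp[[i]],
         head = cols[[i]]$head, fixed = cols[[i]]$fixed)
  })
  residual <- vapply(seq_len(n_cols), function(i) {
    abs(cum_litter[i] - cum_decay[i] - cum_excav[i] - sum(cols[[i]]$mass)) /
      max(1, cum_litter[i])
  }, 0)

  budget_out <- NULL
  if (budget) {
    nrem <- vapply(seq_len(n_cols), function(i) {
      sum(cols[[i]]$mass[grp[[i]] == 0])
    }, 0)
    budget_out <- list(from_year = budget_from_year, stock_start = bud$stock0,
                       new_mass = nrem, loss_acrotelm = bud$lossA,
                       loss_catotelm = bud$lossC, loss_new = bud$lossN,
                       excavated = bud$excav)
  }

  c(yearly, list(final = final, mass_balance_residual = residual,
                 budget = budget_out))
}

# aggregate_thin_layers() with budget-group labels carried along; records
# with different labels are never merged, so the N / A_o / C_s partition
# stays exact.
aggregate_with_groups <- function(column, group, params,
                                  threshold = params$aggregation_threshold,
                                  water_table = column$head) {
  if (length(group) == 0) group <- rep(-1L, length(column$mass))
  stopifnot(length(group) == length(column$mass))
  n <- length(column$mass)
  if (n < 2) return(list(column = column, group = group))
  th <- column$mass / params$bulk_density
  ztop <- column$base + cumsum(th)
  i <- 1L
  while (i < length(column$mass)) {
    th_i <- column$mass[i] / params$bulk_density
    th_j <- column$mass[i + 1] / params$bulk_density
    if (ztop[i + 1] <= water_table && th_i < threshold && th_j < threshold &&
        group[i] == group[i + 1]) {
      msum <- column$mass[i] + column$mass[i + 1]
      column$year_mean[i] <- if (msum > 0) {
        (column$mass[i] * column$year_mean[i] +
           column$mass[i + 1] * column$year_mean[i + 1]) / msum
      } else mean(column$year_mean[i:(i + 1)])
      column$mass[i] <- msum
      column$initial_mass[i] <- column$initial_mass[i] + column$initial_mass[i + 1]
      column$year_old[i] <- min(column$year_old[i], column$year_old[i + 1])
      column$year_young[i] <- max(column$year_young[i], column$year_young[i + 1])
      ztop[i] <- ztop[i + 1]
      drop <- i + 1L
      for (f in c("mass", "initial_mass", "year_young", "year_old", "year_mean")) {
        column[[f]] <- column[[f]][-drop]
      }
      group <- group[-drop]
      ztop <- ztop[-drop]
    } else {
      i <- i + 1L
    }
  }
  list(column = column, group = group)
}
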