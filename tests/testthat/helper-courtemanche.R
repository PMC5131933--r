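# Independent reference integration of the Courtemanche-Ramirez-Nattel
# human atrial model: a plain R derivative function written directly from
# the published equations (alpha/beta rate form, no Rush-Larsen, no
# tabulation) integrated with the stiff solver deSolve::lsoda. Serves as
# the oracle for the package's production stepper.

crn_oracle_initial <- function() {
  c(V = -81.18, m = 2.908e-3, h = 9.649e-1, j = 9.775e-1,
    oa = 3.043e-2, oi = 9.992e-1, ua = 4.966e-3, ui = 9.986e-1,
    xr = 3.296e-5, xs = 1.869e-2, d = 1.367e-4, f = 9.996e-1,
    fca = 7.755e-1, u = 0, v = 1, w = 9.992e-1,
    Nai = 11.17, Ki = 139.0, Cai = 1.013e-4, Caup = 1.488, Carel = 1.488)
}

crn_oracle_rhs <- function(t, y, parms) {
  with(as.list(c(y, parms)), {
    R <- 8.3143; Temp <- 310; Fd <- 96.4867
    RTF <- R * Temp / Fd
    Cm <- 100; Vi <- 13668; Vup <- 1109.52; Vrel <- 96.48
    Ko <- 5.4; Nao <- 140; Cao <- 1.8

    ENa <- RTF * log(Nao / Nai); EK <- RTF * log(Ko / Ki)
    ECa <- RTF / 2 * log(Cao / Cai)

    INa <- 7.8 * gNa_s * m^3 * h * j * (V - ENa)
    IK1 <- 0.09 * gK1_s * (V - EK) / (1 + exp(0.07 * (V + 80)))
    Ito <- 0.1652 * gto_s * oa^3 * oi * (V - EK)
    gkur <- 0.005 + 0.05 / (1 + exp(-(V - 15) / 13))
    IKur <- gKur_s * gkur * ua^3 * ui * (V - EK)
    IKr <- 0.029411765 * xr * (V - EK) / (1 + exp((V + 15) / 22.4))
    IKs <- 0.12941176 * xs^2 * (V - EK)
    ICaL <- 0.12375 * gCaL_s * d * f * fca * (V - 65)
    sigma <- (exp(Nao / 67.3) - 1) / 7
    fNaK <- 1 / (1 + 0.1245 * exp(-0.1 * V / RTF) + 0.0365 * sigma * exp(-V / RTF))
    INaK <- 0.59933874 * fNaK / (1 + (10 / Nai)^1.5) * Ko / (Ko + 1.5)
    INaCa <- 1600 * naca_s *
      (exp(0.35 * V / RTF) * Nai^3 * Cao - exp(-0.65 * V / RTF) * Nao^3 * Cai) /
      ((87.5^3 + 140^3) * (1.38 + 1.8) * (1 + 0.1 * exp(-0.65 * V / RTF)))
    IbNa <- 0.0006744375 * (V - ENa)
    IbCa <- 0.001131 * (V - ECa)
    IpCa <- 0.275 * Cai / (0.0005 + Cai)

    Ist <- if (t >= st_on && t < st_off) -st_amp else 0
    Iion <- INa + IK1 + Ito + IKur + IKr + IKs + ICaL + INaK + INaCa +
      IbNa + IbCa + IpCa
    dV <- -(Iion + Ist)

    # fast sodium gates (Luo-Rudy style rate functions)
    am <- ifelse(abs(V + 47.13) < 1e-9, 3.2,
                 0.32 * (V + 47.13) / (1 - exp(-0.1 * (V + 47.13))))
    bm <- 0.08 * exp(-V / 11)
    if (V >= -40) {
      ah <- 0; bh <- 1 / (0.13 * (1 + exp(-(V + 10.66) / 11.1)))
      aj <- 0
      bj <- 0.3 * exp(-2.535e-7 * V) / (1 + exp(-0.1 * (V + 32)))
    } else {
      ah <- 0.135 * exp(-(V + 80) / 6.8)
      bh <- 3.56 * exp(0.079 * V) + 3.1e5 * exp(0.35 * V)
      aj <- (-1.2714e5 * exp(0.2444 * V) - 3.474e-5 * exp(-0.04391 * V)) *
        (V + 37.78) / (1 + exp(0.311 * (V + 79.23)))
      bj <- 0.1212 * exp(-0.01052 * V) / (1 + exp(-0.1378 * (V + 40.14)))
    }
    dm <- am * (1 - m) - bm * m
    dh <- ah * (1 - h) - bh * h
    dj <- aj * (1 - j) - bj * j

    KQ10 <- 3
    aoa <- 0.65 / (exp(-(V + 10) / 8.5) + exp(-(V - 30) / 59))
    boa <- 0.65 / (2.5 + exp((V + 82) / 17))
    oa_inf <- 1 / (1 + exp(-(V + 20.47) / 17.54))
    doa <- (oa_inf - oa) * KQ10 * (aoa + boa)
    aoi <- 1 / (18.53 + exp((V + 113.7) / 10.95))
    boi <- 1 / (35.56 + exp(-(V + 1.26) / 7.44))
    oi_inf <- 1 / (1 + exp((V + 43.1) / 5.3))
    doi <- (oi_inf - oi) * KQ10 * (aoi + boi)
    ua_inf <- 1 / (1 + exp(-(V + 30.3) / 9.6))
    dua <- (ua_inf - ua) * KQ10 * (aoa + boa)
    aui <- 1 / (21 + exp(-(V - 185) / 28))
    bui <- exp((V - 158) / 16)
    ui_inf <- 1 / (1 + exp((V - 99.45) / 27.48))
    dui <- (ui_inf - ui) * KQ10 * (aui + bui)

    axr <- ifelse(abs(V + 14.1) < 1e-9, 0.0015,
                  0.0003 * (V + 14.1) / (1 - exp(-(V + 14.1) / 5)))
    bxr <- ifelse(abs(V - 3.3328) < 1e-9, 3.7836118e-4,
                  7.3898e-5 * (V - 3.3328) / (exp((V - 3.3328) / 5.1237) - 1))
    xr_inf <- 1 / (1 + exp(-(V + 14.1) / 6.5))
    dxr <- (xr_inf - xr) * (axr + bxr)
    axs <- ifelse(abs(V - 19.9) < 1e-9, 0.00068,
                  4e-5 * (V - 19.9) / (1 - exp(-(V - 19.9) / 17)))
    bxs <- ifelse(abs(V - 19.9) < 1e-9, 0.000315,
                  3.5e-5 * (V - 19.9) / (exp((V - 19.9) / 9) - 1))
    xs_inf <- (1 + exp(-(V - 19.9) / 12.7))^-0.5
    dxs <- (xs_inf - xs) * 2 * (axs + bxs)

    d_inf <- 1 / (1 + exp(-(V + 10) / 8))
    tau_d <- ifelse(abs(V + 10) < 1e-9, 1 / (0.035 * 6.24 * 2),
                    (1 - exp(-(V + 10) / 6.24)) /
                      (0.035 * (V + 10) * (1 + exp(-(V + 10) / 6.24))))
    dd <- (d_inf - d) / tau_d
    f_inf <- 1 / (1 + exp((V + 28) / 6.9))
    tau_f <- 9 / (0.0197 * exp(-0.0337^2 * (V + 10)^2) + 0.02)
    df <- (f_inf - f) / tau_f
    fca_inf <- 1 / (1 + Cai / 0.00035)
    dfca <- (fca_inf - fca) / 2

    Irel <- 30 * u^2 * v * w * (Carel - Cai)
    Itr <- (Caup - Carel) / 180
    Iup <- 0.005 / (1 + 0.00092 / Cai)
    Iupleak <- leak_s * 0.005 * Caup / 15
    Fn <- 1e-12 * Vrel * Irel - 5e-13 / Fd * (0.5 * ICaL - 0.2 * INaCa) * Cm
    u_inf <- 1 / (1 + exp(-(Fn - 3.4175e-13) / 13.67e-16))
    du <- (u_inf - u) / 8
    v_inf <- 1 - 1 / (1 + exp(-(Fn - 6.835e-14) / 13.67e-16))
    tau_v <- 1.91 + 2.09 / (1 + exp(-(Fn - 3.4175e-13) / 13.67e-16))
    dv <- (v_inf - v) / tau_v
    w_inf <- 1 - 1 / (1 + exp(-(V - 40) / 17))
    tau_w <- ifelse(abs(V - 7.9) < 1e-9, 6 * 0.2 / 1.3,
                    6 * (1 - exp(-(V - 7.9) / 5)) /
                      ((1 + 0.3 * exp(-(V - 7.9) / 5)) * (V - 7.9)))
    dw <- (w_inf - w) / tau_w

    f1 <- Cm / (Fd * Vi)
    dNai <- (-3 * INaK - 3 * INaCa - IbNa - INa) * f1
    dKi <- (2 * INaK - IK1 - Ito - IKur - IKr - IKs) * f1
    B1 <- (2 * INaCa - IpCa - ICaL - IbCa) * Cm / (2 * Fd * Vi) +
      (Vup * (Iupleak - Iup) + Irel * Vrel) / Vi
    B2 <- 1 + 0.07 * 0.0005 / (Cai + 0.0005)^2 +
      0.05 * 0.00238 / (Cai + 0.00238)^2
    dCai <- B1 / B2
    dCaup <- Iup - Iupleak - Itr * Vrel / Vup
    dCarel <- (Itr - Irel) / (1 + 10 * 0.8 / (Carel + 0.8)^2)

    list(c(dV, dm, dh, dj, doa, doi, dua, dui, dxr, dxs, dd, df, dfca,
           du, dv, dw, dNai, dKi, dCai, dCaup, dCarel))
  })
}

# integrate one stimulated action potential with lsoda (piecewise around
# the stimulus discontinuity); returns time/V sampled every dt_out
crn_oracle_ap <- function(duration_ms = 600, stim_on = 10, stim_dur = 2,
                          stim_amp = 20, mult = NULL, dt_out = 1) {
  skip_if_not_installed("deSolve")
  p <- c(gNa_s = 1, gto_s = 1, gCaL_s = 1, gKur_s = 1, gK1_s = 1,
         naca_s = 1, leak_s = 1,
         st_on = stim_on, st_off = stim_on + stim_dur, st_amp = stim_amp)
  if (!is.null(mult)) p[names(mult)] <- mult
  breaks <- sort(unique(c(0, stim_on, stim_on + stim_dur, duration_ms)))
  y <- crn_oracle_initial()
  segs <- list()
  for (k in seq_len(length(breaks) - 1)) {
    tt <- sort(unique(c(breaks[k],
                        seq(ceiling(breaks[k] / dt_out) * dt_out,
                            breaks[k + 1], by = dt_out),
                        breaks[k + 1])))
    out <- deSolve::lsoda(y, tt, crn_oracle_rhs, p,
                          rtol = 1e-8, atol = 1e-8, hmax = 1)
    y <- out[nrow(out), -1]
    names(y) <- names(crn_oracle_initial())
    segs[[k]] <- if (k < length(breaks) - 1) out[-nrow(out), , drop = FALSE]
                 else out
  }
  all <- do.call(rbind, segs)
  keep <- abs(all[, "time"] / dt_out - round(all[, "time"] / dt_out)) < 1e-9
  data.frame(time_ms = all[keep, "time"], V = all[keep, "V"])
}
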