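## shared fixtures: built in code at test time

paper_config <- function() acq_config(40e6, 3500, seq(-3, 3))

## small random complex ensemble
random_ensemble <- function(nx = 6, nz = 5, nt = 8, na = 3, seed = 42) {
  cfg <- acq_config(40e6, 3500, seq_len(na))
  set.seed(seed)
  data <- array(complex(real = rnorm(nx * nz * nt * na),
                        imaginary = rnorm(nx * nz * nt * na)),
                c(nx, nz, nt, na))
  iq_ensemble(data, cfg)
}

## compounded series from an explicit (nx, nz, nt) complex array
series_from_array <- function(arr, config = paper_config()) {
  structure(list(data = arr, config = config), class = "compounded_series")
}

## complex tone matrix: one row, nt samples at freq_hz given frame rate
tone_series <- function(freq_hz, nt = 200, fr = 500, amp = 1) {
  amp * matrix(complex(argument = 2 * pi * freq_hz * (0:(nt - 1)) / fr),
               1, nt)
}

## a small noiseless, clutter-free tube simulation (exact phase model)
clean_sim <- function(v = 7.2e-3, nx = 48, nz = 48, nt = 64, seed = 7) {
  ph <- phantom_defaults(nx, nz, v)
  simulate_iq(ph$scene, NULL, NULL, ph$config,
              n_x = nx, n_z = nz, n_frames = nt, seed = seed)
}

## brute-force grid-search oracle for the multibeam solve: sweeps the flow
## direction on a dense grid with refinement; for each candidate direction
## the speed minimizing the sum of squared projection residuals is the
## scalar projection sum(y c)/sum(c^2) with c = cos(theta + theta_i)
grid_search_vector <- function(v_ax, angles_deg) {
  th_i <- angles_deg * pi / 180
  obj <- function(th) {
    cc <- cos(th + th_i)
    v <- sum(v_ax * cc) / sum(cc^2)
    c(v = v, err = sum((v_ax - v * cc)^2))
  }
  ths <- seq(-pi, pi, length.out = 20001)
  best <- c(v = 0, th = 0, err = Inf)
  for (pass in 1:3) {
    for (th in ths) {
      o <- obj(th)
      if (o["err"] < best["err"])
        best <- c(v = unname(o["v"]), th = th, err = unname(o["err"]))
    }
    dth <- diff(ths[1:2])
    ths <- seq(best["th"] - dth, best["th"] + dth, length.out = 201)
  }
  if (best["v"] < 0) {
    best["v"] <- -best["v"]
    best["th"] <- best["th"] + pi
  }
  best
}

## Frobenius-style energy of a (possibly complex) matrix
fnorm2 <- function(x) sum(Mod(x)^2)
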