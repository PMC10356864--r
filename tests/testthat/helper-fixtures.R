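# Shared fixtures and oracles, built in code at test time.

# independent oracle: brute-force enumeration of every rank assignment
enumerate_wilcox_p <- function(a, b) {
  na <- length(a)
  rk <- rank(c(a, b))
  u_obs <- sum(rk[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * length(b) / 2
  combos <- combn(length(rk), na)
  us <- apply(combos, 2, function(ix) sum(rk[ix]) - na * (na + 1) / 2)
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# small chirp + oscillator response pair
make_chirp_pair <- function(f0 = 400, zeta = 0.2, accel = 1000,
                            noise_frac = 0, fs = 10000, duration = 1,
                            seed = 1, down = FALSE) {
  ch <- if (down) gen_chirp_stimulus(1000, 0, duration, fs) else
    gen_chirp_stimulus(0, 1000, duration, fs)
  peak_nm <- accel / (2 * zeta * (2 * pi * f0)^2) * 1e9
  osc <- oscillator_spec(f0, zeta, accel, noise_rms = noise_frac * peak_nm)
  resp <- gen_chirp_response(osc, ch, mode = "envelope", seed = seed)
  list(stimulus = ch, response = resp, osc = osc, peak_nm = peak_nm)
}

# a continuous recording with alternating quiet/stimulus epochs
make_recording <- function(n_epochs = 4, fs = 2000, backscatter_level = 1) {
  section <- fs # 1 s
  total <- (2 * n_epochs + 1) * section
  set.seed(99)
  disp <- rnorm(total, sd = 1)
  onsets <- (2 * seq_len(n_epochs) - 1) # 1, 3, 5, ... seconds
  list(fs = fs, displacement = disp,
       backscatter = rep(backscatter_level, total),
       markers = data.frame(onset_s = onsets,
                            kind = rep(c("upchirp", "downchirp"),
                                       length.out = n_epochs)))
}

# tiny two-group design table for gen_experiment
make_design <- function(n_animals = 2, runs_per_animal = 3,
                        n_force_steps = 0) {
  data.frame(
    group = c("control", "treated"),
    n_animals = n_animals, runs_per_animal = runs_per_animal,
    p_quies = c(0.1, 0.5), p_sso = c(0.8, 0.4), p_transient = c(0.1, 0.1),
    f_osc = c(350, 520), sso_amp = c(400, 150), noise_rms = 4,
    f0 = c(400, 520), zeta = 0.3, accel = 800,
    K_un_per_m = c(200, 1200), force_n = 1.5e-9,
    n_force_steps = n_force_steps)
}
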