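# Default "headline-trend" study configuration.
#
# Calibration constants (they live here, not in code):
#   * corpus.sentiment_trend: the yearly negative/positive post ratio rises
#     geometrically from 0.60 (2004) to 0.60 * 2.33 (2013), with the neutral
#     share held at 0.35, so the true end-to-start Opinion Polarity Ratio
#     trend of the generated stream is exactly 2.33-fold.
#   * panel.visits_growth = 2.41^(1/10), so the national visit total grows by
#     exactly 2.41-fold over the 2004-2014 panel (10 yearly steps).
corpus:
  n_years: 10
  start_year: 2004
  posts_per_year: 2000
  frac_on_topic: 0.5
  sentiment_trend:
  - {year: 2004, p_pos: 0.4062500000, p_neg: 0.2437500000, p_neutral: 0.35}
  - {year: 2005, p_pos: 0.3917724885, p_neg: 0.2582275115, p_neutral: 0.35}
  - {year: 2006, p_pos: 0.3770129055, p_neg: 0.2729870945, p_neutral: 0.35}
  - {year: 2007, p_pos: 0.3620298013, p_neg: 0.2879701987, p_neutral: 0.35}
  - {year: 2008, p_pos: 0.3468855063, p_neg: 0.3031144937, p_neutral: 0.35}
  - {year: 2009, p_pos: 0.3316451301, p_neg: 0.3183548699, p_neutral: 0.35}
  - {year: 2010, p_pos: 0.3163754602, p_neg: 0.3336245398, p_neutral: 0.35}
  - {year: 2011, p_pos: 0.3011437990, p_neg: 0.3488562010, p_neutral: 0.35}
  - {year: 2012, p_pos: 0.2860167810, p_neg: 0.3639832190, p_neutral: 0.35}
  - {year: 2013, p_pos: 0.2710592160, p_neg: 0.3789407840, p_neutral: 0.35}
  lexicon_sizes: {entity: 40, positive: 30, negative: 30, filler: 400}
  emoticon_rate: 0.3
  punct_rate: 0.3
  seed: 1
panel:
  n_regions: 34
  start_year: 2004
  end_year: 2014
  n_factors: 30
  true_beta: {gdp: 0.6, education: 0.4}
  noise_sd: 0.1
  visits_growth: 1.09194736406
  base_total_visits: 1000000
  seed: 1
visits:
  n_records: 50000
  age_mixture:
  - {lo: 25, hi: 35, weight: 0.32}
  - {lo: 0,  hi: 8,  weight: 0.18}
  - {lo: 36, hi: 50, weight: 0.16}
  - {lo: 51, hi: 65, weight: 0.14}
  - {lo: 16, hi: 24, weight: 0.10}
  - {lo: 66, hi: 90, weight: 0.06}
  - {lo: 9,  hi: 15, weight: 0.04}
  seed: 1
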