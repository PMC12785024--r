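name: low_alp
grid: {lo: 400.0, hi: 4000.0, spacing: 0.5}
times: {t0: 0.0, t_end: 33.0, step: 1.5}
rate: 0.08
noise_sd: 0.0002
drift: {slope: 1.0e-06, intercept: 5.0e-04}
metadata: {alp_uM: 1.0, pnpp_mM: 305.0, condition: low}
bands:
- {band_id: B1_1510, center_start: 1509.4, center_end: 1509.4, area_start: 0.45, area_end: 0.45, sigma: 3.5, gamma: 3.0, role: band}
- {band_id: B2_1494, center_start: 1493.9, center_end: 1494.08, area_start: 0.40, area_end: 0.40, sigma: 3.5, gamma: 3.0, role: band}
- {band_id: B3_1345, center_start: 1345.0, center_end: 1345.0, area_start: 0.35, area_end: 0.35, sigma: 3.5, gamma: 3.0, role: band}
- {band_id: B4_1294, center_start: 1295.0, center_end: 1294.0, area_start: 0.30, area_end: 0.30, sigma: 3.5, gamma: 3.0, role: band}
- {band_id: pi_1077, center_start: 1077.0, center_end: 1077.0, area_start: 0.02, area_end: 0.14, sigma: 3.5, gamma: 3.0, role: band}
- {band_id: ctrl_1460, center_start: 1460.0, center_end: 1460.0, area_start: 0.25, area_end: 0.25, sigma: 3.5, gamma: 3.0, role: band}
- {band_id: redis_1606, center_start: 1606.0, center_end: 1606.0, area_start: 0.50, area_end: 0.42, sigma: 3.5, gamma: 3.0, role: band}
- {band_id: redis_1617, center_start: 1617.0, center_end: 1617.0, area_start: 0.08, area_end: 0.16, sigma: 3.5, gamma: 3.0, role: band}
- {band_id: dbl_1583, center_start: 1583.0, center_end: 1583.0, area_start: 0.03, area_end: 0.06, sigma: 3.5, gamma: 3.0, role: band}
- {band_id: dbl_1595, center_start: 1595.0, center_end: 1595.0, area_start: 0.25, area_end: 0.25, sigma: 3.5, gamma: 3.0, role: band}
- {band_id: intf_1045, center_start: 1045.0, center_end: 1045.0, area_start: 0.30, area_end: 0.30, sigma: 3.5, gamma: 3.0, role: band}
- {band_id: intf_925, center_start: 925.0, center_end: 925.0, area_start: 0.20, area_end: 0.20, sigma: 3.5, gamma: 3.0, role: band}
- {band_id: intf_847, center_start: 847.0, center_end: 847.0, area_start: 0.25, area_end: 0.25, sigma: 3.5, gamma: 8.0, role: band}
- {band_id: xh_envelope, center_start: 3390.0, center_end: 3390.0, area_start: 12.0, area_end: 12.0, sigma: 120.0, gamma: 20.0, role: envelope}
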