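pasture_id: synthetic_pasture_1
area_s_ha: 49.1
grazing_days_T: 92
samples_per_day_f: 12
origin_lat: 33.40678
origin_lon: 101.86886
boundary:
  type: Polygon
  coordinates:
  - - - 0.0
      - 0.0
    - - 700.7139217
      - 0.0
    - - 700.7139217
      - 700.7139217
    - - 0.0
      - 700.7139217
    - - 0.0
      - 0.0
campsite:
  type: Point
  coordinates:
  - 350.3569608
  - 350.3569608
  radius_m: 30.0
monitoring_calendar:
- month: 7
  days_grazed: 31
  days_monitored: 4
- month: 8
  days_grazed: 31
  days_monitored: 4
- month: 9
  days_grazed: 30
  days_monitored: 4
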