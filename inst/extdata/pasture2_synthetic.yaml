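pasture_id: synthetic_pasture_2
area_s_ha: 68.66
grazing_days_T: 214
samples_per_day_f: 12
origin_lat: 33.40678
origin_lon: 101.86886
boundary:
  type: Polygon
  coordinates:
  - - - 0.0
      - 0.0
    - - 828.6132994
      - 0.0
    - - 828.6132994
      - 828.6132994
    - - 0.0
      - 828.6132994
    - - 0.0
      - 0.0
campsite:
  type: Point
  coordinates:
  - 414.3066497
  - 414.3066497
  radius_m: 30.0
monitoring_calendar:
- month: 4
  days_grazed: 30
  days_monitored: 4
- month: 5
  days_grazed: 31
  days_monitored: 4
- month: 6
  days_grazed: 30
  days_monitored: 4
- month: 7
  days_grazed: 31
  days_monitored: 4
- month: 8
  days_grazed: 31
  days_monitored: 4
- month: 9
  days_grazed: 30
  days_monitored: 4
- month: 10
  days_grazed: 31
  days_monitored: 4
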