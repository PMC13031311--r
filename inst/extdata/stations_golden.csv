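station_id,lat,lon,date,tmin,tmax
BHM01,52.48,-1.90,1963-01-14,-8.0,-2.0
BHM01,52.48,-1.90,1963-01-15,-12.0,-8.0
BHM01,52.48,-1.90,1963-01-16,-10.5,-5.5
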