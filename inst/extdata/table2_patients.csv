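tumor,volume_ml,k2_ml_min_100ml,k1_ml_min_100ml,segments,injection_velocity_m_s
1a,11.64,54.7,6.9,S2;S3,0.684
1b,2.81,40.2,6.2,S8,2.01
1c,2.67,39.3,4.2,S7;S8,2.01
1d,6.22,38.3,2.3,S7,2.01
1e,15.65,41.4,5.0,S7,2.01
2a,2.53,36.7,3.1,S7,0.52
2b,4.47,42.7,5.2,S8,0.45
3a,63.87,96.7,12.0,S5;S6;S7,1.85
3b,8.92,129.4,11.4,S8,1.85
3c,6.21,103.4,11.9,S7;S8,1.85
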