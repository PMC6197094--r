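temperature_C,direction,c3,c2,c1,c0,r2,note
16,length_of_time,-1.1E-6,5.1E-4,-0.010,2.836,0.997,
19,length_of_time,-3.0E-6,9.6E-4,-6.7E-4,2.313,0.998,linear coefficient -6.7E-4 as printed; neighbouring temperatures have positive coefficients of order 0.05-0.12
22,length_of_time,-5.0E-6,9.6E-4,0.062,2.319,0.996,
25,length_of_time,-1.9E-5,0.003,0.046,2.048,0.998,
28,length_of_time,-4.0E-5,0.005,0.059,1.961,0.995,
31,length_of_time,-5.3E-5,0.005,0.091,2.014,0.996,
34,length_of_time,-7.4E-5,0.006,0.120,2.093,0.998,
16,time_of_length,0.125,-3.832,52.398,-99.977,0.994,
19,time_of_length,0.113,-3.239,38.743,-64.575,0.992,
22,time_of_length,0.046,-1.192,17.993,-32.748,0.994,
25,time_of_length,0.064,-1.624,18.113,-29.789,0.997,
28,time_of_length,0.066,-1.714,17.728,-31.257,0.989,
31,time_of_length,0.042,-1.116,12.502,-21.198,0.985,
34,time_of_length,0.049,-1.352,14.820,-39.324,0.985,
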