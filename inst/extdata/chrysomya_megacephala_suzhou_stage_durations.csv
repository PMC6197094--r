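temperature_C,stage,mean_h,sd_h,n
16,egg,38.9,2.1,4
16,instar1,81.3,4.1,4
16,instar2,84.0,3.8,4
16,instar3,248.2,5.2,4
16,pupa,342.5,17.2,4
16,total,794.8,14.7,4
19,egg,27.2,2.3,4
19,instar1,57.3,4.0,4
19,instar2,58.7,6.1,4
19,instar3,148.2,14.4,4
19,pupa,241.8,13.9,4
19,total,533.2,10.1,4
22,egg,19.2,1.6,4
22,instar1,35.2,6.1,4
22,instar2,40.2,6.1,4
22,instar3,108.6,8.3,4
22,pupa,174.7,8.6,4
22,total,377.8,16.8,4
25,egg,14.8,0.9,4
25,instar1,28.6,2.3,4
25,instar2,32.2,2.3,4
25,instar3,68.0,8.3,4
25,pupa,138.8,9.1,4
25,total,280.8,15.1,4
28,egg,12.2,0.9,4
28,instar1,18.0,2.3,4
28,instar2,22.5,4.2,4
28,instar3,61.2,4.0,4
28,pupa,105.2,6.1,4
28,total,218.9,8.5,4
31,egg,10.3,1.0,4
31,instar1,13.3,2.3,4
31,instar2,16.2,2.3,4
31,instar3,56.8,3.3,4
31,pupa,94.6,4.2,4
31,total,190.8,10.1,4
34,egg,8.5,0.5,4
34,instar1,11.3,1.2,4
34,instar2,13.3,2.3,4
34,instar3,49.6,2.3,4
34,pupa,89.3,4.9,4
34,total,171.8,6.8,4
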