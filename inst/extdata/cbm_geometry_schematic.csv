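code,panel,vertex,x,y
101,front,1,0.42,0.93
101,front,2,0.5,0.93
101,front,3,0.5,1
101,front,4,0.42,1
102,front,1,0.5,0.93
102,front,2,0.58,0.93
102,front,3,0.58,1
102,front,4,0.5,1
103,front,1,0.42,0.86
103,front,2,0.5,0.86
103,front,3,0.5,0.93
103,front,4,0.42,0.93
104,front,1,0.5,0.86
104,front,2,0.58,0.86
104,front,3,0.58,0.93
104,front,4,0.5,0.93
105,front,1,0.44,0.82
105,front,2,0.5,0.82
105,front,3,0.5,0.86
105,front,4,0.44,0.86
106,front,1,0.5,0.82
106,front,2,0.56,0.82
106,front,3,0.56,0.86
106,front,4,0.5,0.86
107,front,1,0.28,0.76
107,front,2,0.42,0.76
107,front,3,0.42,0.82
107,front,4,0.28,0.82
108,front,1,0.42,0.7
108,front,2,0.5,0.7
108,front,3,0.5,0.82
108,front,4,0.42,0.82
109,front,1,0.5,0.7
109,front,2,0.58,0.7
109,front,3,0.58,0.82
109,front,4,0.5,0.82
110,front,1,0.58,0.76
110,front,2,0.72,0.76
110,front,3,0.72,0.82
110,front,4,0.58,0.82
111,front,1,0.28,0.62
111,front,2,0.36,0.62
111,front,3,0.36,0.76
111,front,4,0.28,0.76
112,front,1,0.64,0.62
112,front,2,0.72,0.62
112,front,3,0.72,0.76
112,front,4,0.64,0.76
113,front,1,0.28,0.56
113,front,2,0.36,0.56
113,front,3,0.36,0.62
113,front,4,0.28,0.62
114,front,1,0.64,0.56
114,front,2,0.72,0.56
114,front,3,0.72,0.62
114,front,4,0.64,0.62
115,front,1,0.28,0.46
115,front,2,0.36,0.46
115,front,3,0.36,0.56
115,front,4,0.28,0.56
116,front,1,0.42,0.58
116,front,2,0.5,0.58
116,front,3,0.5,0.7
116,front,4,0.42,0.7
117,front,1,0.5,0.58
117,front,2,0.58,0.58
117,front,3,0.58,0.7
117,front,4,0.5,0.7
118,front,1,0.64,0.46
118,front,2,0.72,0.46
118,front,3,0.72,0.56
118,front,4,0.64,0.56
119,front,1,0.28,0.41
119,front,2,0.36,0.41
119,front,3,0.36,0.46
119,front,4,0.28,0.46
120,front,1,0.38,0.5
120,front,2,0.5,0.5
120,front,3,0.5,0.58
120,front,4,0.38,0.58
121,front,1,0.42,0.42
121,front,2,0.5,0.42
121,front,3,0.5,0.5
121,front,4,0.42,0.5
122,front,1,0.5,0.42
122,front,2,0.58,0.42
122,front,3,0.58,0.5
122,front,4,0.5,0.5
123,front,1,0.5,0.5
123,front,2,0.62,0.5
123,front,3,0.62,0.58
123,front,4,0.5,0.58
124,front,1,0.64,0.41
124,front,2,0.72,0.41
124,front,3,0.72,0.46
124,front,4,0.64,0.46
125,front,1,0.27,0.33
125,front,2,0.37,0.33
125,front,3,0.37,0.41
125,front,4,0.27,0.41
126,front,1,0.4,0.28
126,front,2,0.49,0.28
126,front,3,0.49,0.42
126,front,4,0.4,0.42
127,front,1,0.51,0.28
127,front,2,0.6,0.28
127,front,3,0.6,0.42
127,front,4,0.51,0.42
128,front,1,0.63,0.33
128,front,2,0.73,0.33
128,front,3,0.73,0.41
128,front,4,0.63,0.41
129,front,1,0.4,0.22
129,front,2,0.49,0.22
129,front,3,0.49,0.28
129,front,4,0.4,0.28
130,front,1,0.51,0.22
130,front,2,0.6,0.22
130,front,3,0.6,0.28
130,front,4,0.51,0.28
131,front,1,0.4,0.12
131,front,2,0.49,0.12
131,front,3,0.49,0.22
131,front,4,0.4,0.22
132,front,1,0.51,0.12
132,front,2,0.6,0.12
132,front,3,0.6,0.22
132,front,4,0.51,0.22
133,front,1,0.4,0.07
133,front,2,0.49,0.07
133,front,3,0.49,0.12
133,front,4,0.4,0.12
134,front,1,0.51,0.07
134,front,2,0.6,0.07
134,front,3,0.6,0.12
134,front,4,0.51,0.12
135,front,1,0.36,0.01
135,front,2,0.49,0.01
135,front,3,0.49,0.07
135,front,4,0.36,0.07
136,front,1,0.51,0.01
136,front,2,0.64,0.01
136,front,3,0.64,0.07
136,front,4,0.51,0.07
201,back,1,0.42,0.93
201,back,2,0.5,0.93
201,back,3,0.5,1
201,back,4,0.42,1
202,back,1,0.5,0.93
202,back,2,0.58,0.93
202,back,3,0.58,1
202,back,4,0.5,1
203,back,1,0.42,0.86
203,back,2,0.5,0.86
203,back,3,0.5,0.93
203,back,4,0.42,0.93
204,back,1,0.5,0.86
204,back,2,0.58,0.86
204,back,3,0.58,0.93
204,back,4,0.5,0.93
205,back,1,0.44,0.82
205,back,2,0.5,0.82
205,back,3,0.5,0.86
205,back,4,0.44,0.86
206,back,1,0.5,0.82
206,back,2,0.56,0.82
206,back,3,0.56,0.86
206,back,4,0.5,0.86
207,back,1,0.28,0.76
207,back,2,0.42,0.76
207,back,3,0.42,0.82
207,back,4,0.28,0.82
208,back,1,0.42,0.68
208,back,2,0.5,0.68
208,back,3,0.5,0.82
208,back,4,0.42,0.82
209,back,1,0.5,0.68
209,back,2,0.58,0.68
209,back,3,0.58,0.82
209,back,4,0.5,0.82
210,back,1,0.58,0.76
210,back,2,0.72,0.76
210,back,3,0.72,0.82
210,back,4,0.58,0.82
211,back,1,0.28,0.62
211,back,2,0.36,0.62
211,back,3,0.36,0.76
211,back,4,0.28,0.76
212,back,1,0.42,0.58
212,back,2,0.5,0.58
212,back,3,0.5,0.68
212,back,4,0.42,0.68
213,back,1,0.5,0.58
213,back,2,0.58,0.58
213,back,3,0.58,0.68
213,back,4,0.5,0.68
214,back,1,0.64,0.62
214,back,2,0.72,0.62
214,back,3,0.72,0.76
214,back,4,0.64,0.76
215,back,1,0.28,0.56
215,back,2,0.36,0.56
215,back,3,0.36,0.62
215,back,4,0.28,0.62
216,back,1,0.64,0.56
216,back,2,0.72,0.56
216,back,3,0.72,0.62
216,back,4,0.64,0.62
217,back,1,0.28,0.46
217,back,2,0.36,0.46
217,back,3,0.36,0.56
217,back,4,0.28,0.56
218,back,1,0.42,0.5
218,back,2,0.5,0.5
218,back,3,0.5,0.58
218,back,4,0.42,0.58
219,back,1,0.5,0.5
219,back,2,0.58,0.5
219,back,3,0.58,0.58
219,back,4,0.5,0.58
220,back,1,0.64,0.46
220,back,2,0.72,0.46
220,back,3,0.72,0.56
220,back,4,0.64,0.56
221,back,1,0.28,0.41
221,back,2,0.36,0.41
221,back,3,0.36,0.46
221,back,4,0.28,0.46
222,back,1,0.36,0.44
222,back,2,0.42,0.44
222,back,3,0.42,0.58
222,back,4,0.36,0.58
223,back,1,0.42,0.42
223,back,2,0.5,0.42
223,back,3,0.5,0.5
223,back,4,0.42,0.5
224,back,1,0.5,0.42
224,back,2,0.58,0.42
224,back,3,0.58,0.5
224,back,4,0.5,0.5
225,back,1,0.58,0.44
225,back,2,0.64,0.44
225,back,3,0.64,0.58
225,back,4,0.58,0.58
226,back,1,0.64,0.41
226,back,2,0.72,0.41
226,back,3,0.72,0.46
226,back,4,0.64,0.46
227,back,1,0.27,0.33
227,back,2,0.37,0.33
227,back,3,0.37,0.41
227,back,4,0.27,0.41
228,back,1,0.4,0.28
228,back,2,0.49,0.28
228,back,3,0.49,0.42
228,back,4,0.4,0.42
229,back,1,0.51,0.28
229,back,2,0.6,0.28
229,back,3,0.6,0.42
229,back,4,0.51,0.42
230,back,1,0.63,0.33
230,back,2,0.73,0.33
230,back,3,0.73,0.41
230,back,4,0.63,0.41
231,back,1,0.4,0.22
231,back,2,0.49,0.22
231,back,3,0.49,0.28
231,back,4,0.4,0.28
232,back,1,0.51,0.22
232,back,2,0.6,0.22
232,back,3,0.6,0.28
232,back,4,0.51,0.28
233,back,1,0.4,0.12
233,back,2,0.49,0.12
233,back,3,0.49,0.22
233,back,4,0.4,0.22
234,back,1,0.51,0.12
234,back,2,0.6,0.12
234,back,3,0.6,0.22
234,back,4,0.51,0.22
235,back,1,0.4,0.07
235,back,2,0.49,0.07
235,back,3,0.49,0.12
235,back,4,0.4,0.12
236,back,1,0.51,0.07
236,back,2,0.6,0.07
236,back,3,0.6,0.12
236,back,4,0.51,0.12
237,back,1,0.36,0.01
237,back,2,0.49,0.01
237,back,3,0.49,0.07
237,back,4,0.36,0.07
238,back,1,0.51,0.01
238,back,2,0.64,0.01
238,back,3,0.64,0.07
238,back,4,0.51,0.07
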